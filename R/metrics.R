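#' Confusion counts for one scoring category
#'
#' @param TP,FP,FN nonnegative integers. For link scoring, `FN = WL + ML`
#'   where `WL` (wrong links, pointing at an incorrect target) count as both
#'   FP and FN, and `ML` (missing links) count only as FN.
#' @param WL,ML wrong / missing link counts (links category only).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP = 0L, FP = 0L, FN = 0L, WL = NA_integer_,
                             ML = NA_integer_) {
  if (any(c(TP, FP, FN) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (!is.na(WL) && !is.na(ML) && FN != WL + ML)
    stop("link counts must satisfy FN = WL + ML", call. = FALSE)
  structure(list(TP = as.integer(TP), FP = as.integer(FP), FN = as.integer(FN),
                 WL = as.integer(WL), ML = as.integer(ML)),
            class = "confusion_counts")
}

.add_counts <- function(a, b) {
  confusion_counts(a$TP + b$TP, a$FP + b$FP, a$FN + b$FN,
                   WL = if (is.na(a$WL) && is.na(b$WL)) NA_integer_ else
                     sum(c(a$WL, b$WL), na.rm = TRUE),
                   ML = if (is.na(a$ML) && is.na(b$ML)) NA_integer_ else
                     sum(c(a$ML, b$ML), na.rm = TRUE))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d", x$TP, x$FP, x$FN))
  if (!is.na(x$WL)) cat(sprintf(" (WL=%d ML=%d)", x$WL, x$ML))
  cat("\n")
  invisible(x)
}

#' Mean internuclear distance
#'
#' Mean over centres of the distance to the nearest other centre at the
#' same time step; the reference length for centre-matching radii.
#'
#' @param centres a [centre_set()] (>= 2 centres at one time step).
#' @return Distance in micrometres.
#' @export
mean_internuclear_distance <- function(centres) {
  if (nrow(centres) < 2L) stop("need at least 2 centres", call. = FALSE)
  P <- cbind(centres$x, centres$y, centres$z)
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  mean(apply(D, 1, min))
}

#' Match detected centres to gold-standard centres
#'
#' One-to-one bipartite matching at one time step: pairs farther apart than
#' `r_factor` times the mean internuclear distance of the gold set are
#' inadmissible; among admissible matchings the match count is maximized
#' first, then the total matched distance minimized (so one detected centre
#' can never serve two gold centres). TP = matches, FP = unmatched detected,
#' FN = unmatched gold; TP + FN equals the gold count.
#'
#' @param detected,gold [centre_set()]s at the same time step.
#' @param r_factor matching radius as a fraction of the gold mean
#'   internuclear distance (default 0.5, the midpoint of the accepted
#'   0.2--0.6 working range).
#' @param radius absolute matching radius (um), overriding `r_factor`
#'   (needed when the gold set has fewer than 2 centres).
#' @return list with `matching` (data.frame `detected_id, gold_id,
#'   distance`) and `counts` (a [confusion_counts()]).
#' @export
match_centres <- function(detected, gold, r_factor = 0.5, radius = NULL) {
  if (is.null(radius)) {
    if (r_factor <= 0) stop("r_factor must be > 0", call. = FALSE)
    radius <- r_factor * mean_internuclear_distance(gold)
  }
  nd <- nrow(detected); ng <- nrow(gold)
  empty <- data.frame(detected_id = integer(0), gold_id = integer(0),
                      distance = numeric(0))
  if (nd == 0L || ng == 0L)
    return(list(matching = empty,
                counts = confusion_counts(0L, nd, ng)))
  D <- sqrt(outer(detected$x, gold$x, `-`)^2 +
              outer(detected$y, gold$y, `-`)^2 +
              outer(detected$z, gold$z, `-`)^2)
  adm <- which(D <= radius, arr.ind = TRUE)
  if (!nrow(adm))
    return(list(matching = empty, counts = confusion_counts(0L, nd, ng)))
  # max-cardinality, then min-distance matching via max-weight matching
  C <- radius * (min(nd, ng) + 1) + 1
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nd), rep(TRUE, ng)),
    edges = as.vector(t(cbind(adm[, 1], nd + adm[, 2]))))
  mw <- igraph::max_bipartite_match(g, weights = C - D[adm])
  mt <- mw$matching[seq_len(nd)]
  ok <- !is.na(mt)
  matching <- data.frame(detected_id = detected$id[ok],
                         gold_id = gold$id[mt[ok] - nd],
                         distance = D[cbind(which(ok), mt[ok] - nd)])
  tp <- nrow(matching)
  list(matching = matching,
       counts = confusion_counts(tp, nd - tp, ng - tp))
}

# gold_id -> detected_id lookup from a matching table
.gold_to_det <- function(matching) {
  stats::setNames(matching$detected_id, as.character(matching$gold_id))
}

#' Count link errors between a detected and a gold forest
#'
#' Links are evaluated from `t` to `t - 1` (each centre's mother), and only
#' on the subset of TP centres: for each TP centre at `t` whose gold twin
#' has a mother, the detected link is a TP link if the detected mother is
#' the match of the gold mother; a wrong link (WL, counting as both FP and
#' FN) if a detected mother exists but maps elsewhere; a missing link (ML,
#' FN only) if there is no detected mother.
#'
#' @param matching_t,matching_prev matching tables (from [match_centres()])
#'   at frames `t` and `t - 1`.
#' @param detected_forest,gold_forest [lineage_forest()]s.
#' @param t time index of the daughter frame.
#' @return A [confusion_counts()] with WL/ML filled in.
#' @export
link_errors <- function(matching_t, matching_prev, detected_forest, gold_forest, t) {
  gm <- .mother_vector(gold_forest)
  names(gm) <- as.character(gold_forest$centres$id)
  dm <- .mother_vector(detected_forest)
  names(dm) <- as.character(detected_forest$centres$id)
  g2d_t <- .gold_to_det(matching_t)
  g2d_prev <- .gold_to_det(matching_prev)
  tp <- 0L; wl <- 0L; ml <- 0L
  for (k in seq_len(nrow(matching_t))) {
    gid <- matching_t$gold_id[k]
    gmother <- gm[[as.character(gid)]]
    if (is.na(gmother)) next                       # gold twin has no link
    det_id <- matching_t$detected_id[k]
    det_mother <- dm[[as.character(det_id)]]
    expected <- g2d_prev[as.character(gmother)]    # NA if gold mother not TP
    if (is.na(det_mother)) {
      ml <- ml + 1L
    } else if (!is.na(expected) && det_mother == expected) {
      tp <- tp + 1L
    } else {
      wl <- wl + 1L
    }
  }
  confusion_counts(tp, wl, wl + ml, WL = wl, ML = ml)
}

#' Count mitosis detection errors
#'
#' Assessed within the set of TP centres: a gold division (a mother with
#' two daughters, all three TP) is a TP if the detected forest links the
#' matched mother to both matched daughters, and an FN otherwise (a
#' division with only one daughter link is not properly annotated). A
#' detected division among TP centres with no gold-division counterpart is
#' an FP.
#'
#' @param matching_t,matching_prev matching tables at the daughter frame
#'   `t` and the mother frame `t - 1`.
#' @param detected_forest,gold_forest [lineage_forest()]s.
#' @param t daughter frame index.
#' @return A [confusion_counts()].
#' @export
mitosis_errors <- function(matching_t, matching_prev, detected_forest,
                           gold_forest, t) {
  g2d_t <- .gold_to_det(matching_t)
  g2d_prev <- .gold_to_det(matching_prev)
  glk <- gold_forest$links
  dlk <- detected_forest$links
  gcn <- gold_forest$centres
  dcn <- detected_forest$centres
  # gold divisions with daughters at frame t
  gd <- glk[glk$daughter_id %in% gcn$id[gcn$t == t], , drop = FALSE]
  gtab <- table(gd$mother_id)
  tp <- 0L; fn <- 0L
  matched_det_mothers <- integer(0)
  for (m in as.integer(names(gtab)[gtab == 2L])) {
    kids <- gd$daughter_id[gd$mother_id == m]
    dm <- g2d_prev[as.character(m)]
    dk <- g2d_t[as.character(kids)]
    if (is.na(dm) || any(is.na(dk))) next          # not all three TP
    linked <- all(dk %in% dlk$daughter_id[dlk$mother_id == dm])
    if (linked) { tp <- tp + 1L; matched_det_mothers <- c(matched_det_mothers, dm) }
    else fn <- fn + 1L
  }
  # detected divisions among TP centres with no gold counterpart
  dd <- dlk[dlk$daughter_id %in% dcn$id[dcn$t == t], , drop = FALSE]
  dtab <- table(dd$mother_id)
  d2g_t <- stats::setNames(matching_t$gold_id, as.character(matching_t$detected_id))
  d2g_prev <- stats::setNames(matching_prev$gold_id,
                              as.character(matching_prev$detected_id))
  fp <- 0L
  glk_all <- gold_forest$links
  for (m in as.integer(names(dtab)[dtab == 2L])) {
    if (m %in% matched_det_mothers) next
    kids <- dd$daughter_id[dd$mother_id == m]
    gm <- d2g_prev[as.character(m)]
    gk <- d2g_t[as.character(kids)]
    if (is.na(gm) || any(is.na(gk))) next          # outside the TP subset
    gkids <- glk_all$daughter_id[glk_all$mother_id == gm]
    if (!(length(gkids) == 2L && all(gk %in% gkids))) fp <- fp + 1L
  }
  confusion_counts(tp, fp, fn)
}

#' Derive rates from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `false_detection_rate = FP / (TP + FP)`,
#' `fn_rate = FN / (TP + FN)`. A zero denominator yields `NA` (an
#' undefined-metric marker), never 0.
#'
#' @param counts a [confusion_counts()].
#' @param category `"centres"`, `"links"` or `"mitoses"`.
#' @return An object of class `metric_report` with the three rates.
#' @export
metrics <- function(counts, category = "centres") {
  den_s <- counts$TP + counts$FN
  den_f <- counts$TP + counts$FP
  structure(list(
    sensitivity = if (den_s > 0) counts$TP / den_s else NA_real_,
    false_detection_rate = if (den_f > 0) counts$FP / den_f else NA_real_,
    fn_rate = if (den_s > 0) counts$FN / den_s else NA_real_,
    category = category, counts = counts), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s: sensitivity=%.4f fdr=%.4f fn_rate=%.4f\n",
              x$category, x$sensitivity, x$false_detection_rate, x$fn_rate))
  invisible(x)
}

#' Global lineage score
#'
#' The product of centre-detection sensitivity and linkage sensitivity:
#' linkage alone can look successful even when many centres are missing, so
#' it is weighted by the proportion of detected centres.
#'
#' @param centre_report,link_report [metrics()] reports (or numbers).
#' @return A fraction in `[0, 1]`, or `NA` if either input is undefined.
#' @export
lineage_score <- function(centre_report, link_report) {
  s1 <- if (inherits(centre_report, "metric_report")) centre_report$sensitivity else centre_report
  s2 <- if (inherits(link_report, "metric_report")) link_report$sensitivity else link_report
  if (is.na(s1) || is.na(s2)) return(NA_real_)
  s1 * s2
}

#' Score a reconstructed lineage against a gold standard
#'
#' Per frame, detected centres are matched one-to-one to gold centres
#' (radius `r_factor` times the gold mean internuclear distance of that
#' frame); link and mitosis errors are then counted within the TP subset.
#' Centres outside the gold-standard scope (if any) are ignored on both
#' sides. Counts are aggregated over all scored frames and optionally
#' reported per time window.
#'
#' @param detected a [lineage_forest()].
#' @param gold a [gold_standard()] (or a `lineage_forest`, scored
#'   everywhere).
#' @param r_factor matching radius factor (default 0.5, of the 0.2--0.6
#'   working range).
#' @param time_windows optional list of `c(t_start, t_end)` pairs for a
#'   per-window breakdown.
#' @return list of class `score_report`: `counts` and `metrics` per
#'   category (`centres`, `links`, `mitoses`), `lineage_score`, and
#'   optionally `windows`.
#' @export
score_lineages <- function(detected, gold, r_factor = 0.5, time_windows = NULL) {
  if (inherits(gold, "lineage_forest")) gold <- gold_standard(gold)
  gcn <- gold$forest$centres
  dcn <- detected$centres
  gin <- .in_scope(gcn, gold$scope)
  din <- .in_scope(dcn, gold$scope)
  ts <- sort(unique(gcn$t[gin]))
  matchings <- list()
  cc <- confusion_counts(); lc <- confusion_counts(WL = 0L, ML = 0L)
  mc <- confusion_counts()
  per_frame <- list()
  for (tt in ts) {
    gsub <- gcn[gin & gcn$t == tt, , drop = FALSE]
    dsub <- dcn[din & dcn$t == tt & !dcn$virtual, , drop = FALSE]
    m <- if (nrow(gsub) >= 2L) match_centres(dsub, gsub, r_factor = r_factor)
    else match_centres(dsub, gsub, radius = 1e9)
    matchings[[as.character(tt)]] <- m$matching
    cc <- .add_counts(cc, m$counts)
    lcnt <- NULL; mcnt <- NULL
    if (!is.null(matchings[[as.character(tt - 1L)]])) {
      lcnt <- link_errors(m$matching, matchings[[as.character(tt - 1L)]],
                          detected, gold$forest, tt)
      lc <- .add_counts(lc, lcnt)
      mcnt <- mitosis_errors(m$matching, matchings[[as.character(tt - 1L)]],
                             detected, gold$forest, tt)
      mc <- .add_counts(mc, mcnt)
    }
    per_frame[[as.character(tt)]] <- list(centres = m$counts, links = lcnt,
                                          mitoses = mcnt)
  }
  rep_c <- metrics(cc, "centres"); rep_l <- metrics(lc, "links")
  rep_m <- metrics(mc, "mitoses")
  out <- list(counts = list(centres = cc, links = lc, mitoses = mc),
              metrics = list(centres = rep_c, links = rep_l, mitoses = rep_m),
              lineage_score = lineage_score(rep_c, rep_l))
  if (!is.null(time_windows)) {
    out$windows <- lapply(time_windows, function(wd) {
      agg <- list(centres = confusion_counts(),
                  links = confusion_counts(WL = 0L, ML = 0L),
                  mitoses = confusion_counts())
      for (tt in ts[ts >= wd[1] & ts <= wd[2]]) {
        pf <- per_frame[[as.character(tt)]]
        agg$centres <- .add_counts(agg$centres, pf$centres)
        if (!is.null(pf$links)) agg$links <- .add_counts(agg$links, pf$links)
        if (!is.null(pf$mitoses)) agg$mitoses <- .add_counts(agg$mitoses, pf$mitoses)
      }
      list(window = wd, counts = agg,
           metrics = list(centres = metrics(agg$centres, "centres"),
                          links = metrics(agg$links, "links"),
                          mitoses = metrics(agg$mitoses, "mitoses")))
    })
  }
  class(out) <- "score_report"
  out
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report>\n")
  for (cat_ in c("centres", "links", "mitoses")) {
    m <- x$metrics[[cat_]]
    cat(sprintf("  %-8s TP=%d FP=%d FN=%d  sensitivity=%s fdr=%s\n", cat_,
                m$counts$TP, m$counts$FP, m$counts$FN,
                format(m$sensitivity, digits = 4),
                format(m$false_detection_rate, digits = 4)))
  }
  cat(sprintf("  lineage score = %s\n", format(x$lineage_score, digits = 4)))
  invisible(x)
}
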
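#' Configuration for the simulated-annealing tracker
#'
#' The cost of a candidate lineage forest is a weighted sum of per-term
#' contributions, each expressing one a priori biological requirement:
#' hard structural constraints (single mother, at most two daughters), no
#' disappearance (no cell death at the covered developmental stages),
#' bounded displacement, a minimum interval between successive divisions of
#' a branch, velocity inertia against noise, and symmetric behaviour of
#' sister cells. All distance-based terms are normalized by `d_max` so the
#' weights are unit-free.
#'
#' @param weights named numeric vector; defaults:
#'   `multi_mother = 1e4`, `excess_daughters = 1e4` (hard),
#'   `motherless = 10`, `disappearance = 10`, `displacement = 1`,
#'   `division_interval = 5`, `inertia = 0.5`, `sister_symmetry = 0.5`.
#' @param d_max maximum plausible displacement per frame (um).
#' @param tau_div minimum number of frames expected between successive
#'   divisions along one branch (default 10).
#' @param T0 initial annealing temperature (> 0); the schedule decreases
#'   linearly to 0.
#' @param n_sweeps number of proposal sweeps (each sweep makes one proposal
#'   per linkable centre).
#' @param k_candidates number of nearest predecessors considered as
#'   alternative mothers in rewiring moves.
#' @param L_min repair: isolated trees spanning fewer than `L_min` frames
#'   are deletion candidates (default 3).
#' @param allow_disappearance zero the disappearance term (for systems with
#'   cell death); default `FALSE`.
#' @param seed RNG seed; every run with the same config and input is
#'   bit-reproducible.
#' @return An object of class `anneal_config`.
#' @export
anneal_config <- function(weights = NULL, d_max = 10, tau_div = 10L, T0 = 1,
                          n_sweeps = 50L, k_candidates = 6L, L_min = 3L,
                          allow_disappearance = FALSE, seed = 1L) {
  w <- c(multi_mother = 1e4, excess_daughters = 1e4, motherless = 10,
         disappearance = 10, displacement = 1, division_interval = 5,
         inertia = 0.5, sister_symmetry = 0.5)
  if (!is.null(weights)) {
    unk <- setdiff(names(weights), names(w))
    if (length(unk)) stop("unknown weight(s): ", paste(unk, collapse = ", "),
                          call. = FALSE)
    w[names(weights)] <- weights
  }
  if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)
  if (T0 <= 0) stop("T0 must be > 0", call. = FALSE)
  if (d_max <= 0) stop("d_max must be > 0", call. = FALSE)
  structure(list(weights = w, d_max = d_max, tau_div = as.integer(tau_div),
                 T0 = T0, n_sweeps = as.integer(n_sweeps),
                 k_candidates = as.integer(k_candidates),
                 L_min = as.integer(L_min),
                 allow_disappearance = allow_disappearance,
                 seed = as.integer(seed)),
            class = "anneal_config")
}

.as_centre_table <- function(centres) {
  if (is.data.frame(centres)) return(as.data.frame(centres))
  do.call(rbind, lapply(centres, as.data.frame))
}

#' Initialize lineage links by nearest neighbours
#'
#' Every centre at time `t + 1` links to its nearest centre at time `t`
#' within `d_max` (daughters choose mothers, so a division -- two daughters
#' sharing one mother -- is representable without special cases). The result
#' is not necessarily biologically plausible: centres may end up with more
#' than two daughters; such violations are recorded in the
#' `"violations"` attribute, not rejected.
#'
#' @param centres a data.frame of centres over all frames (columns
#'   `id, t, x, y, z`, ids unique) or a list of per-frame [centre_set()]s.
#' @param d_max maximum link length (um).
#' @return A [lineage_forest()] (out-degree possibly > 2; see above).
#' @export
init_nearest_neighbour <- function(centres, d_max) {
  cn <- .as_centre_table(centres)
  if (anyDuplicated(cn$id)) stop("centre ids must be unique across frames", call. = FALSE)
  ts <- sort(unique(cn$t))
  if (length(ts) < 2L) stop("need at least 2 time steps", call. = FALSE)
  links <- list()
  for (tt in ts[-1]) {
    prev <- cn[cn$t == tt - 1L, ]
    cur <- cn[cn$t == tt, ]
    if (!nrow(prev) || !nrow(cur)) next
    for (i in seq_len(nrow(cur))) {
      d2 <- (prev$x - cur$x[i])^2 + (prev$y - cur$y[i])^2 + (prev$z - cur$z[i])^2
      j <- which.min(d2)
      if (d2[j] <= d_max^2)
        links[[length(links) + 1L]] <- c(prev$id[j], cur$id[i])
    }
  }
  lk <- if (length(links)) {
    m <- do.call(rbind, links)
    data.frame(mother_id = m[, 1], daughter_id = m[, 2])
  } else data.frame(mother_id = integer(0), daughter_id = integer(0))
  f <- lineage_forest(cn, lk, validate = FALSE)
  outdeg <- if (nrow(lk)) table(lk$mother_id) else integer(0)
  attr(f, "violations") <- list(excess_daughters = sum(pmax(outdeg - 2L, 0L)))
  f
}

# --- cost machinery -------------------------------------------------------

# Vectorized cost of a forest from its links table (the reference
# implementation; the annealer's incremental deltas are tested against it).

#' Evaluate the tracking cost of a lineage forest
#'
#' @param forest a [lineage_forest()] (out-degree violations allowed, e.g.
#'   fresh nearest-neighbour initializations).
#' @param config an [anneal_config()].
#' @return list of class `cost_breakdown` with `total` and `per_term`
#'   (weighted contributions; `total = sum(per_term)`).
#' @export
forest_cost <- function(forest, config) {
  cn <- forest$centres; lk <- forest$links
  w <- config$weights; dmax <- config$d_max
  row <- seq_len(nrow(cn)); names(row) <- as.character(cn$id)
  tmax <- max(cn$t)
  mi <- row[as.character(lk$mother_id)]
  di <- row[as.character(lk$daughter_id)]
  indeg <- tabulate(di, nbins = nrow(cn))
  outdeg <- tabulate(mi, nbins = nrow(cn))
  P <- cbind(cn$x, cn$y, cn$z)
  term <- c(motherless = sum(cn$t > 0 & indeg == 0L),
            disappearance = if (config$allow_disappearance) 0 else
              sum(cn$t < tmax & outdeg == 0L),
            multi_mother = sum(pmax(indeg - 1L, 0L)),
            excess_daughters = sum(pmax(outdeg - 2L, 0L)),
            displacement = if (length(mi))
              sum(rowSums((P[di, , drop = FALSE] - P[mi, , drop = FALSE])^2)) / dmax^2
            else 0,
            division_interval = 0, inertia = 0, sister_symmetry = 0)
  # first mother per centre (used for branch walks when in-degree > 1)
  mother <- rep(NA_integer_, nrow(cn))
  if (length(di)) mother[rev(di)] <- rev(mi)
  if (length(mi)) {
    # inertia: consecutive link pairs sharing the middle centre
    has_gm <- !is.na(mother[mi])
    if (any(has_gm)) {
      m2 <- mi[has_gm]; d2 <- di[has_gm]; gm <- mother[m2]
      v1 <- P[m2, , drop = FALSE] - P[gm, , drop = FALSE]
      v2 <- P[d2, , drop = FALSE] - P[m2, , drop = FALSE]
      term["inertia"] <- sum(rowSums((v2 - v1)^2)) / dmax^2
    }
    # sister symmetry: all daughter pairs of each multi-daughter mother
    mm <- which(outdeg >= 2L)
    ss <- 0
    for (m in mm) {
      ks <- di[mi == m]
      pr <- utils::combn(ks, 2L)
      ss <- ss + sum(vapply(seq_len(ncol(pr)), function(j)
        sum((P[pr[1, j], ] - P[pr[2, j], ])^2), numeric(1)))
    }
    term["sister_symmetry"] <- ss / dmax^2
    # divisions too close along one branch
    divs <- which(outdeg >= 2L)
    cnt <- 0L
    for (v in divs) {
      cur <- mother[v]
      while (!is.na(cur) && (cn$t[v] - cn$t[cur]) < config$tau_div) {
        if (outdeg[cur] >= 2L) cnt <- cnt + 1L
        cur <- mother[cur]
      }
    }
    term["division_interval"] <- cnt
  }
  wt <- w[c("motherless", "disappearance", "multi_mother", "excess_daughters",
            "displacement", "division_interval", "inertia", "sister_symmetry")]
  per <- term * wt
  structure(list(total = sum(per), per_term = per), class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> total = %.6g\n", x$total))
  nz <- x$per_term[x$per_term > 0]
  if (length(nz)) for (n in names(nz)) cat(sprintf("  %s: %.6g\n", n, nz[n]))
  invisible(x)
}

# Internal annealing over the mother-assignment representation.
# state lives in the enclosing frame of .run_anneal; helpers mutate via <<-.
.run_anneal <- function(cn, mother0, config, n_sweeps, T0) {
  n <- nrow(cn)
  tvec <- cn$t
  tmax <- max(tvec)
  P <- cbind(cn$x, cn$y, cn$z)
  w <- config$weights; dmax2 <- config$d_max^2; tau_div <- config$tau_div
  w_dis <- if (config$allow_disappearance) 0 else w[["disappearance"]]
  mother <- mother0
  kids <- rep(list(integer(0)), n)
  for (i in which(!is.na(mother)))
    kids[[mother[i]]] <- c(kids[[mother[i]]], i)

  # candidate mothers: k nearest predecessors within d_max
  cand <- rep(list(integer(0)), n)
  by_t <- split(seq_len(n), tvec)
  tkeys <- as.integer(names(by_t))
  for (ki in seq_along(tkeys)[-1]) {
    if (tkeys[ki] - 1L != tkeys[ki - 1L]) next
    prev <- by_t[[ki - 1L]]
    for (i in by_t[[ki]]) {
      d2 <- (P[prev, 1] - P[i, 1])^2 + (P[prev, 2] - P[i, 2])^2 +
        (P[prev, 3] - P[i, 3])^2
      ok <- which(d2 <= dmax2)
      if (length(ok)) {
        ord <- ok[order(d2[ok])]
        cand[[i]] <- prev[utils::head(ord, config$k_candidates)]
      }
    }
  }

  loc_centre <- function(i) {
    # motherless + displacement + inertia at i
    m <- mother[i]
    if (is.na(m)) return(if (tvec[i] > 0L) w[["motherless"]] else 0)
    v2 <- P[i, ] - P[m, ]
    val <- w[["displacement"]] * sum(v2 * v2) / dmax2
    gm <- mother[m]
    if (!is.na(gm)) {
      dv <- v2 - (P[m, ] - P[gm, ])
      val <- val + w[["inertia"]] * sum(dv * dv) / dmax2
    }
    val
  }
  loc_mother <- function(m) {
    ks <- kids[[m]]
    nk <- length(ks)
    val <- 0
    if (nk == 0L) { if (tvec[m] < tmax) val <- val + w_dis }
    if (nk > 2L) val <- val + w[["excess_daughters"]] * (nk - 2L)
    if (nk >= 2L) {
      for (a in seq_len(nk - 1L)) for (b in seq.int(a + 1L, nk)) {
        dv <- P[ks[a], ] - P[ks[b], ]
        val <- val + w[["sister_symmetry"]] * sum(dv * dv) / dmax2
      }
    }
    val
  }
  up_count <- function(v) {
    cnt <- 0L
    cur <- mother[v]
    while (!is.na(cur) && (tvec[v] - tvec[cur]) < tau_div) {
      if (length(kids[[cur]]) >= 2L) cnt <- cnt + 1L
      cur <- mother[cur]
    }
    cnt
  }
  div_region <- function(roots) {
    roots <- unique(roots[!is.na(roots)])
    if (!length(roots)) return(0)
    seen <- integer(0)
    tot <- 0
    for (r in roots) {
      queue <- r
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        if (v %in% seen) next
        seen <- c(seen, v)
        if (length(kids[[v]]) >= 2L) tot <- tot + up_count(v)
        for (k in kids[[v]])
          if (tvec[k] - tvec[r] <= tau_div) queue <- c(queue, k)
      }
    }
    w[["division_interval"]] * tot
  }
  local_cost <- function(i, ms) {
    val <- loc_centre(i)
    for (k in kids[[i]]) val <- val + loc_centre(k)
    for (m in unique(ms[!is.na(ms)])) val <- val + loc_mother(m)
    val + div_region(c(i, ms))
  }
  set_mother <- function(i, new_m) {
    old_m <- mother[i]
    if (!is.na(old_m)) kids[[old_m]] <<- kids[[old_m]][kids[[old_m]] != i]
    mother[i] <<- new_m
    if (!is.na(new_m)) kids[[new_m]] <<- c(kids[[new_m]], i)
    old_m
  }
  try_move <- function(i, new_m) {
    old_m <- mother[i]
    ms <- c(old_m, new_m)
    before <- local_cost(i, ms)
    set_mother(i, new_m)
    after <- local_cost(i, ms)
    list(delta = after - before, old_m = old_m)
  }

  full_cost <- function() {
    tot <- 0
    for (i in seq_len(n)) tot <- tot + loc_centre(i) + loc_mother(i)
    for (v in seq_len(n)) if (length(kids[[v]]) >= 2L)
      tot <- tot + w[["division_interval"]] * up_count(v)
    tot
  }

  linkable <- which(tvec > 0L)
  cost_cur <- full_cost()
  best_cost <- cost_cur
  best_mother <- mother
  M <- max(1L, n_sweeps * length(linkable))
  trace <- numeric(0)
  if (length(linkable)) for (step in seq_len(M)) {
    Temp <- T0 * (1 - (step - 1) / M)
    i <- linkable[sample.int(length(linkable), 1L)]
    u <- stats::runif(1)
    if (is.na(mother[i])) {
      if (!length(cand[[i]])) next
      new_m <- cand[[i]][sample.int(length(cand[[i]]), 1L)]
      mv <- try_move(i, new_m)
      delta <- mv$delta
      accept <- delta <= 0 || (Temp > 0 && stats::runif(1) < exp(-delta / Temp))
      if (!accept) set_mother(i, mv$old_m) else cost_cur <- cost_cur + delta
    } else if (u < 0.6) {                       # rewire among candidates
      ch <- cand[[i]][cand[[i]] != mother[i]]
      if (!length(ch)) next
      new_m <- ch[sample.int(length(ch), 1L)]
      mv <- try_move(i, new_m)
      delta <- mv$delta
      accept <- delta <= 0 || (Temp > 0 && stats::runif(1) < exp(-delta / Temp))
      if (!accept) set_mother(i, mv$old_m) else cost_cur <- cost_cur + delta
    } else if (u < 0.8) {                       # delete the link
      mv <- try_move(i, NA_integer_)
      delta <- mv$delta
      accept <- delta <= 0 || (Temp > 0 && stats::runif(1) < exp(-delta / Temp))
      if (!accept) set_mother(i, mv$old_m) else cost_cur <- cost_cur + delta
    } else {                                    # swap mothers with a peer
      peers <- by_t[[as.character(tvec[i])]]
      peers <- peers[peers != i & !is.na(mother[peers])]
      if (!length(peers)) next
      j <- peers[sample.int(length(peers), 1L)]
      mi_old <- mother[i]; mj_old <- mother[j]
      if (identical(mi_old, mj_old)) next
      if (sum((P[i, ] - P[mj_old, ])^2) > dmax2 ||
          sum((P[j, ] - P[mi_old, ])^2) > dmax2) next
      mv1 <- try_move(i, mj_old)
      mv2 <- try_move(j, mi_old)
      delta <- mv1$delta + mv2$delta
      accept <- delta <= 0 || (Temp > 0 && stats::runif(1) < exp(-delta / Temp))
      if (!accept) { set_mother(j, mv2$old_m); set_mother(i, mv1$old_m) }
      else cost_cur <- cost_cur + delta
    }
    if (cost_cur < best_cost - 1e-12) {
      best_cost <- cost_cur
      best_mother <- mother
    }
    if (step %% max(1L, length(linkable)) == 0L) trace <- c(trace, cost_cur)
  }
  # restore the best state seen
  mother <- best_mother
  kids <- rep(list(integer(0)), n)
  for (i in which(!is.na(mother)))
    kids[[mother[i]]] <- c(kids[[mother[i]]], i)
  # enforce the hard daughter constraint exactly: keep the two daughters with
  # the smallest displacement, detach the rest (strictly cost-decreasing
  # given the dominant hard weight)
  repeat {
    bad <- which(lengths(kids) > 2L)
    if (!length(bad)) break
    for (m in bad) {
      ks <- kids[[m]]
      d2 <- vapply(ks, function(k) sum((P[k, ] - P[m, ])^2), numeric(1))
      drop <- ks[order(d2)][-(1:2)]
      for (k in drop) set_mother(k, NA_integer_)
    }
  }
  list(mother = mother, trace = trace)
}

.forest_from_mother <- function(cn, mother) {
  has <- !is.na(mother)
  links <- data.frame(mother_id = cn$id[mother[has]], daughter_id = cn$id[has])
  lineage_forest(cn, links)
}

#' Optimize lineage links by simulated annealing
#'
#' Proposes random link modifications (rewire a centre's mother among its
#' nearest predecessors, delete a link, create a link for a motherless
#' centre, swap the mothers of two contemporaneous centres). Cost-decreasing
#' moves are always accepted; cost-increasing ones with probability
#' `min(1, exp(-delta / T))`, the temperature falling linearly from `T0` to
#' 0 over the run. The returned forest satisfies the hard constraints
#' (single mother, at most two daughters) exactly and is deterministic for
#' a fixed config.
#'
#' @param forest an initialized [lineage_forest()] (e.g. from
#'   [init_nearest_neighbour()]).
#' @param config an [anneal_config()].
#' @return The optimized `lineage_forest`; attributes `cost` (final
#'   [forest_cost()] breakdown) and `cost_trace` (cost per sweep).
#' @export
anneal <- function(forest, config) {
  cn <- forest$centres
  row <- seq_len(nrow(cn)); names(row) <- as.character(cn$id)
  # collapse any multi-mother input to the nearest mother
  mother0 <- rep(NA_integer_, nrow(cn))
  if (nrow(forest$links)) {
    mi <- row[as.character(forest$links$mother_id)]
    di <- row[as.character(forest$links$daughter_id)]
    d2 <- (cn$x[mi] - cn$x[di])^2 + (cn$y[mi] - cn$y[di])^2 + (cn$z[mi] - cn$z[di])^2
    ord <- order(d2, decreasing = TRUE)
    mother0[di[ord]] <- mi[ord]
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(config$seed)
  res <- .run_anneal(cn, mother0, config, config$n_sweeps, config$T0)
  out <- .forest_from_mother(cn, res$mother)
  attr(out, "cost") <- forest_cost(out, config)
  attr(out, "cost_trace") <- res$trace
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Repair a lineage forest
#'
#' Builds a candidate edit set -- delete isolated trees spanning fewer than
#' `L_min` frames, and bridge one-frame gaps (a track ending at `t` and a
#' track starting at `t + 2` within `2 * d_max`) by inserting a virtual
#' centre at the spatial midpoint at `t + 1` -- then selects the edit subset
#' by the same annealing machinery, scored with [forest_cost()]. Inserted
#' centres carry `virtual = TRUE`.
#'
#' @param forest an annealed [lineage_forest()].
#' @param config an [anneal_config()].
#' @return The repaired `lineage_forest` with attribute `edits` (data.frame
#'   of applied edits).
#' @export
repair <- function(forest, config) {
  cn <- forest$centres; lk <- forest$links
  tmax <- max(cn$t)
  mother <- .mother_vector(forest)
  outdeg <- tabulate(match(lk$mother_id, cn$id), nbins = nrow(cn))
  # isolated short trees
  g <- igraph::make_empty_graph(n = nrow(cn), directed = FALSE)
  if (nrow(lk))
    g <- igraph::add_edges(g, rbind(match(lk$mother_id, cn$id),
                                    match(lk$daughter_id, cn$id)))
  comp <- igraph::components(g)$membership
  spans <- tapply(cn$t, comp, function(v) max(v) - min(v) + 1L)
  short <- as.integer(names(spans)[spans < config$L_min])
  edits <- list()
  for (s in short)
    edits[[length(edits) + 1L]] <- list(type = "delete", comp = s)
  # one-frame gaps
  ends <- which(outdeg == 0L & cn$t < tmax)
  starts <- which(is.na(mother) & cn$t >= 1L)
  for (e in ends) for (s in starts) {
    if (cn$t[s] != cn$t[e] + 2L) next
    d <- sqrt((cn$x[e] - cn$x[s])^2 + (cn$y[e] - cn$y[s])^2 + (cn$z[e] - cn$z[s])^2)
    if (d <= 2 * config$d_max)
      edits[[length(edits) + 1L]] <- list(type = "bridge", e = e, s = s)
  }
  if (!length(edits)) {
    attr(forest, "edits") <- data.frame()
    return(forest)
  }
  apply_edits <- function(b) {
    keep <- rep(TRUE, nrow(cn))
    for (k in which(b)) if (edits[[k]]$type == "delete")
      keep[comp == edits[[k]]$comp] <- FALSE
    cn2 <- cn[keep, , drop = FALSE]
    lk2 <- lk[lk$mother_id %in% cn2$id & lk$daughter_id %in% cn2$id, , drop = FALSE]
    nid <- max(cn$id) + 1L
    for (k in which(b)) {
      ed <- edits[[k]]
      if (ed$type != "bridge") next
      eid <- cn$id[ed$e]; sid <- cn$id[ed$s]
      if (!(eid %in% cn2$id) || !(sid %in% cn2$id)) next
      if (eid %in% lk2$mother_id || sid %in% lk2$daughter_id) next
      cn2 <- rbind(cn2, data.frame(id = nid, t = cn$t[ed$e] + 1L,
                                   x = (cn$x[ed$e] + cn$x[ed$s]) / 2,
                                   y = (cn$y[ed$e] + cn$y[ed$s]) / 2,
                                   z = (cn$z[ed$e] + cn$z[ed$s]) / 2,
                                   intensity = 0, virtual = TRUE))
      lk2 <- rbind(lk2, data.frame(mother_id = c(eid, nid),
                                   daughter_id = c(nid, sid)))
      nid <- nid + 1L
    }
    lineage_forest(cn2, lk2, validate = FALSE)
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(config$seed)
  b <- rep(FALSE, length(edits))
  cost_cur <- forest_cost(apply_edits(b), config)$total
  best <- b; best_cost <- cost_cur
  M <- max(50L, 20L * length(edits))
  for (step in seq_len(M)) {
    Temp <- config$T0 * (1 - (step - 1) / M)
    k <- sample.int(length(edits), 1L)
    b2 <- b; b2[k] <- !b2[k]
    c2 <- forest_cost(apply_edits(b2), config)$total
    delta <- c2 - cost_cur
    if (delta <= 0 || (Temp > 0 && stats::runif(1) < exp(-delta / Temp))) {
      b <- b2; cost_cur <- c2
      if (cost_cur < best_cost - 1e-12) { best <- b; best_cost <- cost_cur }
    }
  }
  out <- apply_edits(best)
  validate_forest(out)
  applied <- which(best)
  attr(out, "edits") <- if (length(applied))
    data.frame(type = vapply(edits[applied], `[[`, "", "type")) else data.frame()
  attr(out, "cost") <- forest_cost(out, config)
  out
}

#' Track centres through time
#'
#' Convenience wrapper running the three tracking stages in sequence:
#' nearest-neighbour initialization, simulated-annealing optimization, and
#' repair.
#'
#' @param centres per-frame centres (see [init_nearest_neighbour()]).
#' @param config an [anneal_config()].
#' @return A repaired [lineage_forest()].
#' @export
track_centres <- function(centres, config) {
  repair(anneal(init_nearest_neighbour(centres, config$d_max), config), config)
}

#' Propagate labels down a lineage forest
#'
#' Every descendant (following links forward through divisions) inherits
#' the label of its closest labelled ancestor; explicitly labelled centres
#' keep their own label for their subtree. Conflicts are impossible because
#' each centre has a single mother.
#'
#' @param forest a [lineage_forest()].
#' @param labels named vector: names are centre ids (as characters), values
#'   labels.
#' @return Named character vector mapping every reached centre id to its
#'   label.
#' @export
propagate_labels <- function(forest, labels) {
  cn <- forest$centres
  ids <- as.character(cn$id)
  unk <- setdiff(names(labels), ids)
  if (length(unk)) stop("unknown centre id(s): ", paste(unk, collapse = ", "),
                        call. = FALSE)
  lab <- stats::setNames(rep(NA_character_, nrow(cn)), ids)
  lab[names(labels)] <- as.character(labels)
  mother <- .mother_vector(forest)
  ord <- order(cn$t)
  for (i in ord) {
    if (!is.na(lab[i])) next
    m <- mother[i]
    if (!is.na(m)) {
      ml <- lab[as.character(m)]
      if (!is.na(ml)) lab[i] <- ml
    }
  }
  lab[!is.na(lab)]
}
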
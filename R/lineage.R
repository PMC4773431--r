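#' Construct a lineage forest
#'
#' A lineage forest is the union of disjoint cell-lineage trees: nodes are
#' nucleus centres over all time steps, edges link a mother centre at time
#' `t` to a daughter centre at `t + 1`. Every centre has at most one mother
#' and at most two daughters; the graph is acyclic by construction because
#' links always advance time by one frame.
#'
#' @param centres data.frame with columns `id` (unique integer), `t`
#'   (integer time index >= 0), `x`, `y`, `z` (um), and optionally
#'   `intensity` (>= 0) and `virtual` (logical: inserted by repair, not
#'   detected).
#' @param links data.frame with columns `mother_id`, `daughter_id`; may have
#'   zero rows.
#' @param validate check the forest invariants (default `TRUE`).
#' @return An object of class `lineage_forest`.
#' @export
lineage_forest <- function(centres, links = NULL, validate = TRUE) {
  centres <- as.data.frame(centres)
  if (is.null(centres$intensity)) centres$intensity <- 0
  if (is.null(centres$virtual)) centres$virtual <- FALSE
  need <- c("id", "t", "x", "y", "z", "intensity", "virtual")
  miss <- setdiff(need, names(centres))
  if (length(miss)) stop("centres missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  centres <- centres[need]
  centres$id <- as.integer(centres$id)
  centres$t <- as.integer(centres$t)
  centres$virtual <- as.logical(centres$virtual)
  if (is.null(links)) links <- data.frame(mother_id = integer(0), daughter_id = integer(0))
  links <- as.data.frame(links)[c("mother_id", "daughter_id")]
  links$mother_id <- as.integer(links$mother_id)
  links$daughter_id <- as.integer(links$daughter_id)
  f <- structure(list(centres = centres, links = links), class = "lineage_forest")
  if (validate) validate_forest(f)
  f
}

#' Check lineage-forest invariants
#'
#' Errors unless: centre ids are unique; every link joins existing centres at
#' consecutive time steps (mother at `t`, daughter at `t + 1`); in-degree is
#' at most 1 (single mother) and out-degree at most 2 (at most two
#' daughters).
#'
#' @param forest a [lineage_forest()].
#' @return The forest, invisibly.
#' @export
validate_forest <- function(forest) {
  cn <- forest$centres; lk <- forest$links
  if (anyDuplicated(cn$id)) stop("duplicate centre id(s): ",
                                 paste(unique(cn$id[duplicated(cn$id)]), collapse = ", "),
                                 call. = FALSE)
  tmap <- cn$t; names(tmap) <- as.character(cn$id)
  if (nrow(lk)) {
    unk <- setdiff(c(lk$mother_id, lk$daughter_id), cn$id)
    if (length(unk)) stop("link(s) reference unknown centre id(s): ",
                          paste(unk, collapse = ", "), call. = FALSE)
    dt <- tmap[as.character(lk$daughter_id)] - tmap[as.character(lk$mother_id)]
    if (any(dt != 1L))
      stop("links must span exactly one frame (mother at t, daughter at t+1)",
           call. = FALSE)
    indeg <- table(lk$daughter_id)
    if (any(indeg > 1L))
      stop("centre(s) with more than one mother: ",
           paste(names(indeg)[indeg > 1L], collapse = ", "), call. = FALSE)
    outdeg <- table(lk$mother_id)
    if (any(outdeg > 2L))
      stop("centre(s) with more than two daughters: ",
           paste(names(outdeg)[outdeg > 2L], collapse = ", "), call. = FALSE)
  }
  invisible(forest)
}

#' @export
print.lineage_forest <- function(x, ...) {
  nt <- length(unique(x$centres$t))
  ndiv <- if (nrow(x$links)) sum(table(x$links$mother_id) == 2L) else 0L
  cat(sprintf("<lineage_forest> %d centres over %d time steps, %d links, %d divisions, %d virtual\n",
              nrow(x$centres), nt, nrow(x$links), ndiv, sum(x$centres$virtual)))
  invisible(x)
}

# mother id per centre (NA for roots), aligned with forest$centres rows
.mother_vector <- function(forest) {
  m <- rep(NA_integer_, nrow(forest$centres))
  if (nrow(forest$links)) {
    i <- match(forest$links$daughter_id, forest$centres$id)
    m[i] <- forest$links$mother_id
  }
  m
}

#' Write a lineage forest to CSV
#'
#' One row per centre: `id, t, x, y, z, mother_id, virtual`, with
#' `mother_id = -1` for roots. Positions are stored with 6 decimal digits
#' (the documented round-trip precision). [read_lineage()] is the inverse.
#'
#' @param forest a [lineage_forest()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(forest, path) {
  validate_forest(forest)
  cn <- forest$centres
  mid <- .mother_vector(forest)
  mid[is.na(mid)] <- -1L
  df <- data.frame(id = cn$id, t = cn$t,
                   x = sprintf("%.6f", cn$x), y = sprintf("%.6f", cn$y),
                   z = sprintf("%.6f", cn$z),
                   mother_id = mid, virtual = as.integer(cn$virtual))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a lineage forest from CSV
#'
#' Accepts the format written by [write_lineage()]; an optional `curated`
#' column (used by gold-standard files) is preserved as an attribute.
#'
#' @param path CSV file path.
#' @return A [lineage_forest()].
#' @export
read_lineage <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "t", "x", "y", "z", "mother_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("lineage file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate centre id(s) in lineage file: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  unk <- setdiff(df$mother_id[df$mother_id >= 0], df$id)
  if (length(unk))
    stop("row(s) reference unknown mother_id: ", paste(unk, collapse = ", "),
         call. = FALSE)
  centres <- data.frame(id = df$id, t = df$t, x = df$x, y = df$y, z = df$z,
                        intensity = if (is.null(df$intensity)) 0 else df$intensity,
                        virtual = if (is.null(df$virtual)) FALSE else df$virtual > 0)
  has_m <- df$mother_id >= 0
  links <- data.frame(mother_id = df$mother_id[has_m], daughter_id = df$id[has_m])
  f <- lineage_forest(centres, links)
  if (!is.null(df$curated)) attr(f, "curated") <- df$curated > 0
  f
}

#' Bundle a curated lineage as a gold standard
#'
#' @param forest a validated [lineage_forest()] used as the error-free
#'   reference.
#' @param scope optional data.frame of space-time boxes restricting where
#'   scoring is valid, columns `xmin, xmax, ymin, ymax, zmin, zmax, tmin,
#'   tmax` (um and frames). `NULL` scores everywhere.
#' @return An object of class `gold_standard`.
#' @export
gold_standard <- function(forest, scope = NULL) {
  validate_forest(forest)
  if (!is.null(scope)) {
    scope <- as.data.frame(scope)
    need <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax", "tmin", "tmax")
    miss <- setdiff(need, names(scope))
    if (length(miss)) stop("scope missing columns: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    if (any(scope$xmax <= scope$xmin | scope$ymax <= scope$ymin |
              scope$zmax <= scope$zmin | scope$tmax < scope$tmin))
      stop("degenerate scope box", call. = FALSE)
  }
  structure(list(forest = forest, scope = scope), class = "gold_standard")
}

# logical vector: which centres fall inside the gold-standard scope
.in_scope <- function(centres, scope) {
  if (is.null(scope)) return(rep(TRUE, nrow(centres)))
  inside <- rep(FALSE, nrow(centres))
  for (i in seq_len(nrow(scope))) {
    b <- scope[i, ]
    inside <- inside |
      (centres$x >= b$xmin & centres$x <= b$xmax &
         centres$y >= b$ymin & centres$y <= b$ymax &
         centres$z >= b$zmin & centres$z <= b$zmax &
         centres$t >= b$tmin & centres$t <= b$tmax)
  }
  inside
}
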
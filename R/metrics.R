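#' Landmark error distances between matched POI sets
#'
#' Euclidean distance `rho = sqrt((x2-x1)^2 + (y2-y1)^2 + (z2-z1)^2)` per
#' matched name, plus the median error distance (MED) the pipeline reports
#' as its headline accuracy number. Points are matched by name; both sets
#' must carry the same space tag.
#'
#' @param p1,p2 [POISet()]s with identical name sets.
#' @return object of class `poi_report`: list with `per_poi` (named um
#'   distances, in `p1` order) and `median` (um).
#' @export
poi_distance <- function(p1, p2) {
  stopifnot(inherits(p1, "POISet"), inherits(p2, "POISet"))
  if (!setequal(p1$names, p2$names))
    stop("POI name sets differ: ",
         paste(symdiff_chr(p1$names, p2$names), collapse = ", "))
  if (!identical(p1$space, p2$space))
    stop("POI sets live in different spaces (", p1$space, " vs ",
         p2$space, ")")
  m <- match(p1$names, p2$names)
  d <- sqrt(rowSums((p1$coords - p2$coords[m, , drop = FALSE])^2))
  names(d) <- p1$names
  structure(list(per_poi = d, median = stats::median(d)),
            class = "poi_report")
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' @export
print.poi_report <- function(x, ...) {
  cat(sprintf("POI distances (n = %d): median %.2f um\n",
              length(x$per_poi), x$median))
  print(round(x$per_poi, 2))
  invisible(x)
}

#' @export
as.data.frame.poi_report <- function(x, ...) {
  data.frame(name = names(x$per_poi), distance_um = unname(x$per_poi),
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.dice_report <- function(x, ...) {
  data.frame(id = names(x$per_region), dice = unname(x$per_region),
             stringsAsFactors = FALSE)
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report a `poi_report` or `dice_report`.
#' @param path_prefix output path without extension; `<prefix>.csv` and
#'   `<prefix>.json` are written.
#' @return the two paths, invisibly.
#' @export
write_eval_report <- function(report, path_prefix) {
  df <- as.data.frame(report)
  csv <- paste0(path_prefix, ".csv")
  json <- paste0(path_prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  payload <- unclass(report)
  payload$per_poi <- as.list(payload$per_poi)
  payload$per_region <- as.list(payload$per_region)
  payload <- payload[!vapply(payload, is.null, logical(1))]
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Dice overlap of two binary masks
#'
#' `Dice = 2 |A intersect B| / (|A| + |B|)`.
#'
#' @param a,b binary masks: [LabelVolume()]s (nonzero = foreground) or
#'   logical/numeric arrays of one grid.
#' @return Dice score in `[0, 1]`; both-empty masks are an error (the
#'   score is undefined there).
#' @export
dice <- function(a, b) {
  ma <- as_mask(a); mb <- as_mask(b)
  if (!identical(dim(ma), dim(mb))) stop("masks on different grids")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) stop("Dice undefined: both masks empty")
  2 * sum(ma & mb) / (na + nb)
}

as_mask <- function(x) {
  if (inherits(x, "LabelVolume")) return(x$labels != 0L)
  if (inherits(x, "Volume")) return(x$data != 0)
  x != 0
}

#' Per-region Dice scores between two label volumes
#'
#' @param a,b [LabelVolume()]s on one grid.
#' @param ids label ids to score; default: all nonzero ids present in `a`.
#' @return object of class `dice_report`: `per_region` (named scores; NA
#'   for ids absent from both), `median` over the present ids.
#' @export
dice_by_region <- function(a, b, ids = NULL) {
  stopifnot(inherits(a, "LabelVolume"), inherits(b, "LabelVolume"))
  if (!identical(dim(a$labels), dim(b$labels)))
    stop("label volumes on different grids")
  if (is.null(ids))
    ids <- setdiff(sort(unique(as.vector(a$labels))), 0L)
  scores <- vapply(ids, function(id) {
    ma <- a$labels == id; mb <- b$labels == id
    if (!any(ma) && !any(mb)) return(NA_real_)
    2 * sum(ma & mb) / (sum(ma) + sum(mb))
  }, numeric(1))
  names(scores) <- as.character(ids)
  structure(list(per_region = scores,
                 median = stats::median(scores, na.rm = TRUE),
                 missing = as.integer(ids[is.na(scores)])),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice by region (n = %d): median %.3f\n",
              sum(!is.na(x$per_region)), x$median))
  print(round(x$per_region, 3))
  if (length(x$missing))
    cat("missing from both volumes:", paste(x$missing, collapse = " "), "\n")
  invisible(x)
}

#' STAPLE fusion of repeated binary segmentations
#'
#' Simultaneous Truth and Performance Level Estimation (binary EM): the
#' E-step computes the posterior foreground probability of every voxel
#' from the current per-rater sensitivities `p_j` and specificities `q_j`
#' and the prior; the M-step re-estimates `p_j`, `q_j` from the posterior.
#' Iterates until the parameter change drops below `tol`. The consensus
#' mask thresholds the posterior at 0.5.
#'
#' @param raters list of >= 2 binary masks (arrays or [LabelVolume()]s) on
#'   one grid.
#' @param tol convergence tolerance on `max |delta p, delta q|`
#'   (default 1e-6).
#' @param max_iter EM iteration cap (default 100).
#' @param prior prior foreground probability; default the mean rater
#'   foreground fraction.
#' @param init initial sensitivity/specificity for every rater
#'   (default 0.99).
#' @return object of class `staple_fit`: `consensus` (logical array),
#'   `posterior`, `sensitivity`, `specificity`, `iterations`, `converged`,
#'   `low_confidence` (TRUE when the posterior hugs the prior, i.e. the
#'   raters carry no consistent signal).
#' @export
staple_fuse <- function(raters, tol = 1e-6, max_iter = 100L, prior = NULL,
                        init = 0.99) {
  if (length(raters) < 2) stop("need at least 2 raters")
  masks <- lapply(raters, as_mask)
  dd <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), dd))
    stop("rater masks on different grids")
  D <- vapply(masks, as.vector, logical(length(masks[[1]])))
  nv <- nrow(D); J <- ncol(D)
  if (all(!D)) stop("degenerate input: all raters empty")
  if (is.null(prior)) prior <- mean(colMeans(D))
  p <- rep(init, J); q <- rep(init, J)
  W <- numeric(nv)
  it <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step in log space for numerical safety
    la <- log(prior); lb <- log1p(-prior)
    for (j in seq_len(J)) {
      dj <- D[, j]
      la <- la + ifelse(dj, log(p[j]), log1p(-p[j]))
      lb <- lb + ifelse(dj, log1p(-q[j]), log(q[j]))
    }
    W <- 1 / (1 + exp(lb - la))
    sw <- sum(W); swc <- nv - sw
    p_new <- vapply(seq_len(J), function(j) {
      s <- sum(W[D[, j]])
      if (sw > 0) s / sw else 0.5
    }, numeric(1))
    q_new <- vapply(seq_len(J), function(j) {
      s <- sum((1 - W)[!D[, j]])
      if (swc > 0) s / swc else 0.5
    }, numeric(1))
    p_new <- pmin(pmax(p_new, 1e-7), 1 - 1e-7)
    q_new <- pmin(pmax(q_new, 1e-7), 1 - 1e-7)
    delta <- max(abs(c(p_new - p, q_new - q)))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  low_conf <- mean(abs(W - prior)) < 0.05
  structure(list(consensus = array(W >= 0.5, dim = dd),
                 posterior = array(W, dim = dd),
                 sensitivity = p, specificity = q, iterations = it,
                 converged = converged, low_confidence = low_conf,
                 prior = prior),
            class = "staple_fit")
}

#' @export
print.staple_fit <- function(x, ...) {
  cat(sprintf("STAPLE fusion: %d raters, %d EM iterations (%s)\n",
              length(x$sensitivity), x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat("  sensitivity:", paste(round(x$sensitivity, 3), collapse = " "), "\n")
  cat("  specificity:", paste(round(x$specificity, 3), collapse = " "), "\n")
  if (x$low_confidence)
    cat("  note: posterior stays near the prior; low-confidence consensus\n")
  invisible(x)
}
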
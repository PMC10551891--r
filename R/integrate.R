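#' Weighted combination of two abundance datasets
#'
#' Proteins quantified in both datasets are combined as a weighted geometric
#' mean: `10^((1-w) * log10(a) + w * log10(b))` (protein abundances are
#' log-distributed, so averaging in log space is the natural choice; set
#' `space = "linear"` for an arithmetic weighted mean as a sensitivity
#' check). Proteins present in only one dataset are carried over scaled by
#' that side's weight mass (`1-w` or `w`), so coverage is the union of the
#' two. A shared protein with a zero value on one side is treated as absent
#' from that side. `w = 0` returns `a` exactly and `w = 1` returns `b`
#' exactly; the result is renormalized to 1e6 ppm.
#'
#' @param a,b `abundance_dataset`s over the same namespace.
#' @param w weight of `b`, in \[0, 1\].
#' @param space `"log"` (default, geometric mean) or `"linear"`.
#' @return An `abundance_dataset`.
#' @export
combine_datasets <- function(a, b, w, space = c("log", "linear")) {
  stopifnot(w >= 0, w <= 1)
  space <- match.arg(space)
  if (w == 0) return(a)
  if (w == 1) return(b)
  pa <- a$ppm; pb <- b$ppm
  ids <- union(names(pa), names(pb))
  va <- pa[ids]; va[is.na(va)] <- 0
  vb <- pb[ids]; vb[is.na(vb)] <- 0
  both <- va > 0 & vb > 0
  out <- numeric(length(ids))
  out[both] <- if (space == "log")
    10^((1 - w) * log10(va[both]) + w * log10(vb[both]))
  else (1 - w) * va[both] + w * vb[both]
  onlya <- va > 0 & !both
  onlyb <- vb > 0 & !both
  out[onlya] <- (1 - w) * va[onlya]
  out[onlyb] <- w * vb[onlyb]
  names(out) <- ids
  to_ppm(out[out > 0 | (va == 0 & vb == 0)],
         organism = a$organism, tissue = a$tissue,
         method = sprintf("combined(%s, %s, w=%g)", a$method, b$method, w))
}

#' Integrate multiple datasets by greedy weighted averaging
#'
#' Datasets are sorted by their interaction z-score (descending; ties broken
#' by name) and the best one seeds the merge. Each subsequent dataset is
#' combined with the running merge at `n_weights` equally spaced weights
#' over \[0, 1\]; the candidate with the highest interaction z-score is kept
#' (ties go to the smallest weight, i.e. the established merge). Because the
#' grid contains w = 0, the integrated score never falls below the best
#' single dataset's score under the same seed. The same shuffle seed is used
#' for every candidate so weight selection compares like with like.
#'
#' @param datasets named list of `abundance_dataset`s (names are used in the
#'   trace and for tie-breaking).
#' @param net an `interaction_network`.
#' @param n_weights number of grid points over \[0, 1\] (default 11:
#'   0.0, 0.1, ..., 1.0).
#' @param n_shuffles shuffles per z-score evaluation (default 500).
#' @param seed integer seed (required).
#' @param space combination space, see [combine_datasets()].
#' @return A list of class `"integration_result"`: `integrated` (an
#'   `abundance_dataset` with its final score and the merge recorded),
#'   `component_weights` (named vector, the weight each dataset received at
#'   its merge step; the seed dataset gets 1), and `trace` (one row per
#'   dataset: name, initial z, chosen weight, z after its merge).
#' @export
integrate_datasets <- function(datasets, net, n_weights = 11L,
                               n_shuffles = 500L, seed,
                               space = c("log", "linear")) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  space <- match.arg(space)
  stopifnot(length(datasets) >= 1L, n_weights >= 2L)
  if (is.null(names(datasets)) || anyNA(names(datasets)) ||
      any(!nzchar(names(datasets))) || anyDuplicated(names(datasets)))
    stop("datasets must be a uniquely named list", call. = FALSE)

  z0 <- vapply(datasets, function(d)
    interaction_zscore(d, net, n_shuffles, seed)$z, numeric(1))
  ord <- order(-z0, names(datasets))
  datasets <- datasets[ord]; z0 <- z0[ord]

  grid <- seq(0, 1, length.out = n_weights)
  merged <- datasets[[1L]]
  best_z <- z0[[1L]]
  weights <- setNames(numeric(length(datasets)), names(datasets))
  weights[1L] <- 1
  trace <- data.frame(dataset = names(datasets), initial_z = z0,
                      best_weight = NA_real_, best_z = NA_real_,
                      stringsAsFactors = FALSE)
  trace$best_weight[1L] <- 1; trace$best_z[1L] <- best_z

  for (k in seq_along(datasets)[-1L]) {
    zs <- vapply(grid, function(w)
      interaction_zscore(combine_datasets(merged, datasets[[k]], w, space),
                         net, n_shuffles, seed)$z, numeric(1))
    pick <- which.max(zs)  # first max: tie goes to the smaller weight
    merged <- combine_datasets(merged, datasets[[k]], grid[pick], space)
    best_z <- zs[pick]
    weights[k] <- grid[pick]
    trace$best_weight[k] <- grid[pick]; trace$best_z[k] <- best_z
  }

  merged$score <- best_z
  merged$method <- "integrated"
  structure(list(integrated = merged, component_weights = weights,
                 trace = trace, seed = seed),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("integration of %d dataset(s), final z = %.3f (seed %s)\n",
              nrow(x$trace), x$integrated$score, format(x$seed)))
  print(x$trace)
  invisible(x)
}
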
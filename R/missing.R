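#' @name missing_simulator
#' @title Missingness simulation (MCAR and probabilistic limit of detection)
#' @description
#' [induce_mcar()] blanks exactly `round(pct * n)` positions uniformly at
#' random. [induce_plod()] emulates a probabilistic limit of detection: the
#' same number of positions is blanked, but allocated across the tertiles of
#' the value distribution as 40% lower / 50% middle / 10% upper, so lower
#' concentrations are far more likely to go missing (an MNAR mechanism).
#' Rounding is half-away-from-zero and the upper share takes the remainder,
#' so the tertile counts always sum to the total. If a share exceeds its
#' tertile's size, the overflow spills to the adjacent lower-rank tertile
#' first, then to the remaining one.
#'
#' Both functions consume the current R RNG stream (`set.seed()` before the
#' call for reproducible masks).
NULL

# even rank-based tertile membership: first ceil(n/3) ranks are "lower",
# ties in values resolved by position (stable order)
tertile_sizes <- function(n) {
  n1 <- ceiling(n / 3)
  n2 <- ceiling((n - n1) / 2)
  c(n1, n2, n - n1 - n2)
}

#' Tertile membership of each value
#'
#' Rank-based, distribution-free strata: the lowest `ceiling(n/3)` values
#' form tertile 1, and so on; value ties are broken by position.
#'
#' @param values Numeric vector without missing values.
#' @return Integer vector in `1:3` (1 = lower tertile).
#' @export
tertile_of <- function(values) {
  if (anyNA(values)) stop("'values' must be complete")
  n <- length(values)
  tert <- integer(n)
  tert[order(values)] <- rep.int(1:3, tertile_sizes(n))
  tert
}

new_missing_mask <- function(indices, mechanism, pct, n, tertile_counts) {
  structure(list(indices = sort(as.integer(indices)), mechanism = mechanism,
                 pct = pct, n = as.integer(n),
                 tertile_counts = as.integer(tertile_counts)),
            class = "missing_mask")
}

#' @export
print.missing_mask <- function(x, ...) {
  cat("<missing_mask>", x$mechanism, "| n =", x$n, "| masked:",
      length(x$indices), sprintf("(pct = %g)", x$pct),
      "| tertile counts:", paste(x$tertile_counts, collapse = "/"), "\n")
  invisible(x)
}

#' @rdname missing_simulator
#' @param values Complete numeric vector.
#' @param pct Target missing fraction in `[0, 1)`.
#' @return A list of class `"missing_mask"`: `indices` (sorted positions to
#'   blank), `mechanism`, `pct`, `n`, `tertile_counts` (masked positions per
#'   value tertile).
#' @export
induce_mcar <- function(values, pct) {
  n <- length(values)
  if (anyNA(values)) stop("'values' must be complete")
  if (pct < 0 || pct >= 1) stop("'pct' must lie in [0, 1)")
  M <- round_half_up(pct * n)
  if (M >= n && M > 0) stop("pct * n rounds to n; cannot blank every value")
  idx <- if (M > 0) sample.int(n, M) else integer(0)
  tert <- tertile_of(values)
  new_missing_mask(idx, "MCAR", pct, n, tabulate(tert[idx], 3L))
}

#' @rdname missing_simulator
#' @export
induce_plod <- function(values, pct) {
  n <- length(values)
  if (anyNA(values)) stop("'values' must be complete")
  if (pct < 0 || pct >= 1) stop("'pct' must lie in [0, 1)")
  M <- round_half_up(pct * n)
  if (M > n) stop("cannot blank more values than exist")
  if (M == 0) return(new_missing_mask(integer(0), "PLoD", pct, n, c(0L, 0L, 0L)))
  sizes <- tertile_sizes(n)
  want <- c(round_half_up(0.4 * M), round_half_up(0.5 * M), 0)
  want[3] <- M - want[1] - want[2]
  spill_order <- list(c(2L, 3L), c(1L, 3L), c(2L, 1L))
  for (i in 1:3) {
    if (want[i] > sizes[i]) {
      excess <- want[i] - sizes[i]
      want[i] <- sizes[i]
      for (j in spill_order[[i]]) {
        take <- min(sizes[j] - want[j], excess)
        want[j] <- want[j] + take
        excess <- excess - take
        if (excess == 0) break
      }
      if (excess > 0) stop("infeasible PLoD allocation")  # M <= n: unreachable
    }
  }
  tert <- tertile_of(values)
  idx <- unlist(lapply(1:3, function(i) {
    members <- which(tert == i)
    members[sample.int(length(members), want[i])]
  }))
  new_missing_mask(idx, "PLoD", pct, n, want)
}

#' Apply a missingness mask to a vector or to one table column
#'
#' @param x Numeric vector, or a metabolite table if `target_id` is given.
#' @param mask A `"missing_mask"`.
#' @param target_id Metabolite id to blank when `x` is a table.
#' @return `x` with the masked positions set to `NA`.
#' @export
apply_mask <- function(x, mask, target_id = NULL) {
  if (!inherits(mask, "missing_mask")) stop("'mask' must be a missing_mask")
  if (is.null(target_id)) {
    x[mask$indices] <- NA_real_
  } else {
    x[mask$indices, target_id] <- NA_real_
  }
  x
}
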
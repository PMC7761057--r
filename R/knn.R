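#' kNN imputation over observations with variable pre-selection
#'
#' For each missing cell (sample i, metabolite j), donors are the samples
#' with metabolite j observed. The distance from i to a donor is the
#' Euclidean distance over the auxiliary metabolites of j that are observed
#' in *both* rows, rescaled by sqrt(n_aux_total / n_aux_shared) so that rows
#' sharing fewer auxiliaries do not look spuriously close. The imputed value
#' aggregates the observed j-values of the `k` nearest donors (all donors if
#' fewer than `k`); distance ties at rank k are resolved by ascending sample
#' id (C collation), so the result is deterministic and invariant to row
#' order. Each target is imputed against the original table, never against
#' partially imputed data, so targets can be processed in any order.
#'
#' A recipient sharing no observed auxiliary with any donor falls back to
#' the median (or mean) of all observed j-values; such fallbacks are counted
#' in the `"fallback_count"` attribute.
#'
#' @param table Numeric matrix (samples x metabolites), log-standardized.
#' @param aux Named list of `"aux_set"` objects, one per target to impute
#'   (names = target ids).
#' @param k Number of nearest donors, default 10.
#' @param aggregate `"median"` (default) or `"mean"` of the donor values.
#' @return The completed matrix (only listed targets are filled); attribute
#'   `"fallback_count"` counts zero-shared-auxiliary fallbacks.
#' @export
knn_obs_sel_impute <- function(table, aux, k = 10L, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  validate_metabolite_table(table)
  agg <- if (aggregate == "median") stats::median else mean
  out <- table
  fallback <- 0L
  srank <- id_rank(rownames(table))
  for (s in aux) {
    j <- s$target_id
    if (!j %in% colnames(table)) stop("unknown target id: ", j)
    miss <- which(is.na(table[, j]))
    if (length(miss) == 0L) next
    donors <- which(!is.na(table[, j]))
    if (length(donors) == 0L)
      stop("internal error: target '", j, "' has no observed values")
    A <- table[, s$aux_ids, drop = FALSE]
    p_tot <- length(s$aux_ids)
    y_don <- table[donors, j]
    if (!anyNA(A)) {
      # complete auxiliaries: one dense distance computation per target
      Ar <- A[miss, , drop = FALSE]
      Ad <- A[donors, , drop = FALSE]
      D2 <- outer(rowSums(Ar^2), rowSums(Ad^2), "+") - 2 * tcrossprod(Ar, Ad)
      D2[D2 < 0] <- 0  # numerical negatives
      for (ii in seq_along(miss)) {
        ord <- order(D2[ii, ], srank[donors])
        out[miss[ii], j] <- agg(y_don[utils::head(ord, k)])
      }
    } else {
      for (i in miss) {
        diffs <- sweep(A[donors, , drop = FALSE], 2L, A[i, ])
        sq <- diffs^2
        shared <- rowSums(!is.na(sq))
        ss <- rowSums(sq, na.rm = TRUE)
        d2 <- ifelse(shared == 0L, Inf, ss * p_tot / shared)
        ok <- which(is.finite(d2))
        if (length(ok) == 0L) {
          out[i, j] <- agg(y_don)
          fallback <- fallback + 1L
        } else {
          ord <- ok[order(d2[ok], srank[donors[ok]])]
          out[i, j] <- agg(y_don[utils::head(ord, k)])
        }
      }
    }
  }
  structure(out, fallback_count = fallback)
}
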
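# Independent oracles, deliberately naive: sum-formula Pearson, exhaustive
# kNN enumeration, SVD pseudoinverse least squares. They never call the
# implementation paths they check.

bf_pearson <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# exhaustive kNN-obs-sel: triple loop over targets, recipients, donors
bf_knn <- function(table, aux, k) {
  out <- table
  sids <- rownames(table)
  for (s in aux) {
    j <- s$target_id
    p_tot <- length(s$aux_ids)
    for (i in seq_len(nrow(table))) {
      if (!is.na(table[i, j])) next
      donors <- which(!is.na(table[, j]))
      dist <- rep(Inf, length(donors))
      for (di in seq_along(donors)) {
        dsum <- 0; shared <- 0
        for (a in s$aux_ids) {
          xi <- table[i, a]; xd <- table[donors[di], a]
          if (!is.na(xi) && !is.na(xd)) {
            dsum <- dsum + (xi - xd)^2
            shared <- shared + 1
          }
        }
        if (shared > 0) dist[di] <- sqrt(dsum * p_tot / shared)
      }
      finite <- which(is.finite(dist))
      if (length(finite) == 0) {
        out[i, j] <- median(table[donors, j])
      } else {
        ord <- finite[order(dist[finite],
                            match(sids[donors[finite]],
                                  sort(sids, method = "radix")))]
        sel <- ord[seq_len(min(k, length(ord)))]
        out[i, j] <- median(table[donors[sel], j])
      }
    }
  }
  out
}

# least squares metabolite coefficient via SVD pseudoinverse
pinv_ols <- function(covariates, metabolite) {
  X <- cbind(1, covariates$age, covariates$sex, metabolite)
  y <- covariates$BMI
  sv <- svd(X)
  dpos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  beta <- sv$v[, dpos] %*% ((t(sv$u[, dpos]) %*% y) / sv$d[dpos])
  beta[4]
}

random_table <- function(n, p, miss_frac = 0.2, seed = 1) {
  set.seed(seed)
  tb <- matrix(exp(rnorm(n * p, 2, 0.6)), n, p,
               dimnames = list(sprintf("S%02d", seq_len(n)),
                               sprintf("M%02d", seq_len(p))))
  if (miss_frac > 0) {
    k <- round(miss_frac * n * p)
    tb[sample.int(n * p, k)] <- NA
  }
  tb
}

make_aux_set <- function(target, aux_ids, abs_r = NULL) {
  absr <- if (is.null(abs_r)) rev(seq_along(aux_ids)) / (length(aux_ids) + 1)
          else abs_r
  structure(list(target_id = target, aux_ids = aux_ids, aux_abs_r = absr,
                 mean_abs_r = mean(absr), topped_up = FALSE),
            class = "aux_set")
}
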
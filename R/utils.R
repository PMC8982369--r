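# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Seeded 80/20 split of a set of ids
#'
#' The same `(ids, seed)` pair always yields the same split; the elastic-net
#' and GBM tuners share it so both models see the identical train/test
#' partition of the reference set.
#'
#' @param ids character vector of animal ids.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_80_20 <- function(ids, test_fraction = 0.2, seed = 1) {
  stopifnot(length(ids) >= 5, test_fraction > 0, test_fraction < 1)
  with_seed(seed, {
    n_test <- max(1L, round(length(ids) * test_fraction))
    test <- sort(sample(ids, n_test))
    list(train = setdiff(ids, test), test = test)
  })
}

# Largest-remainder apportionment of `total` into quotas proportional to w.
largest_remainder <- function(w, total) {
  stopifnot(all(w >= 0), sum(w) > 0, total >= 0)
  exact <- total * w / sum(w)
  q <- floor(exact)
  left <- total - sum(q)
  if (left > 0) {
    ord <- order(exact - q, decreasing = TRUE)
    q[ord[seq_len(left)]] <- q[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(q), names(w))
}

# Draw sigma^2 from a scaled inverse chi-square(df, scale) distribution.
rscinvchisq <- function(n, df, scale) {
  df * scale / stats::rchisq(n, df = df)
}

# Population (denominator n) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
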
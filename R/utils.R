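# Internal helpers shared across modules.

# Deterministic child seed for a named stage, fanned out from one global
# seed. Keeps every stochastic stage independently reproducible while a
# single integer controls the whole run. Result stays inside 32-bit range.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587L) + 1L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Sample standard deviation (n - 1 denominator) that errors informatively
# on degenerate input.
sample_sd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Cannot standardize: input has zero (or undefined) variance.")
  }
  s
}

# Weighted mean / variance with frequency-style weights.
wtd_mean <- function(x, w) sum(w * x) / sum(w)
wtd_var <- function(x, w) {
  m <- wtd_mean(x, w)
  sum(w * (x - m)^2) / sum(w) * sum(w) / (sum(w) - sum(w^2) / sum(w))
}

# Build a design tibble with missing-indicator coding: NA entries are set
# to zero and a companion 0/1 indicator column `<name>_missing` is added
# for every covariate with any missingness. One shared builder is used by
# both the propensity and outcome models.
add_missing_indicators <- function(data, covariates) {
  out <- data
  added <- character(0)
  for (v in covariates) {
    x <- out[[v]]
    if (anyNA(x)) {
      ind <- paste0(v, "_missing")
      out[[ind]] <- as.numeric(is.na(x))
      x[is.na(x)] <- 0
      out[[v]] <- x
      added <- c(added, ind)
    }
  }
  list(data = out, indicator_columns = added)
}

# Drop linearly dependent columns of a numeric design matrix, reporting
# the names dropped.
drop_aliased <- function(X) {
  qr_x <- qr(X)
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  list(X = X[, sort(keep), drop = FALSE], dropped = dropped)
}
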
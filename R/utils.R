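# internal helpers shared across modules

# run code under a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable log(sum(exp(x)))
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "hearload_config_error")
}

stop_validation <- function(msg) {
  abort(msg, class = "hearload_validation_error")
}

check_fraction <- function(x, field, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || !hi_ok) {
    stop_config(field, sprintf("must be a single number in [0, %s)",
                               if (allow_one) "1]" else "1"))
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != floor(x)) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

# genotype matrices are variants x samples; missing calls are NA
check_geno_matrix <- function(gt) {
  if (!is.matrix(gt) || is.null(rownames(gt)) || is.null(colnames(gt))) {
    stop_validation(
      "genotypes must be a variants x samples matrix with variant ids as rownames and sample ids as colnames")
  }
  invisible(gt)
}
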
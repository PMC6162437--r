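# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# validate a genes x samples expression matrix; returns it invisibly
check_expression_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg), call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("`%s` must have gene rownames and sample colnames", arg), call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(sprintf("`%s` has duplicated gene ids", arg), call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(sprintf("`%s` has duplicated sample ids", arg), call. = FALSE)
  if (anyNA(x))
    stop(sprintf("`%s` contains missing values; dense matrices are required", arg), call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 1L)
    stop(sprintf("`%s` needs >= 2 genes and >= 1 sample", arg), call. = FALSE)
  invisible(x)
}

check_scalar_number <- function(x, arg, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single number in [%s, %s]", arg, min, max), call. = FALSE)
  invisible(x)
}

check_count <- function(x, arg, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", arg, min), call. = FALSE)
  invisible(as.integer(x))
}

# population standard deviation (divide by n, not n - 1)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
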
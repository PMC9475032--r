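# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  if (x < min || x > max)
    stopf("'%s' must be in [%s, %s], got %s", name, min, max, x)
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_num(x, name, min = min)
  if (x != round(x)) stopf("'%s' must be an integer count", name)
  invisible(as.integer(x))
}

#' @importFrom withr with_seed
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stage-local seed from a global seed; double arithmetic avoids
# 32-bit overflow for large inputs, result stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 977 + as.numeric(offset) * 7919) %%
               2147483629)
}

is_mito_gene <- function(gene_ids, prefix = "MT-") {
  startsWith(gene_ids, prefix)
}
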
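# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr local_seed
with_seed_if <- function(seed, .env = parent.frame()) {
  # seed = NULL means "use the current RNG stream"
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = .env)
  invisible(NULL)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Count exact (non-overlapping-agnostic) occurrences of a pattern
#' @noRd
count_matches <- function(subject, pattern) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) 0L else length(m)
}

#' Largest-remainder apportionment of `total` into integer parts
#'
#' Splits `total` proportionally to `weights` so the parts sum exactly to
#' `total`; ties in remainders are broken toward the earlier (larger) class.
#' @noRd
largest_remainder <- function(weights, total) {
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  rem <- quota - base
  left <- total - sum(base)
  if (left > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Integer percentages summing to 100 (largest remainder)
#' @noRd
percent_lr <- function(counts) {
  largest_remainder(counts, 100L)
}

#' Canonical unordered genotype string "A/B"
#' @noRd
geno_str <- function(a, b) {
  paste(sort(c(a, b), method = "radix"), collapse = "/")
}

#' Split "A/B" into its two allele labels
#' @noRd
geno_alleles <- function(g) {
  strsplit(g, "/", fixed = TRUE)[[1]]
}

is_missing_geno <- function(g) {
  is.na(g) | g == "." | g == ""
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
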
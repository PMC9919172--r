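# shared test helpers: independent oracles and small fixture builders

vkey <- function(df) {
  paste(df$reference, df$position, df$ref_allele, df$alt_allele)
}

# independent row-by-row re-statement of the cascade predicates
brute_force_survivors <- function(merged, min_cov_pet = 13,
                                  min_cov_rob = 5) {
  ok <- logical(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    r <- merged[i, ]
    ok[i] <- round(r$alt_freq, 1) == 100 &&
      r$coverage >= min_cov_pet &&
      r$rob_coverage > 0 &&
      !is.na(r$rob_ref_freq) && round(r$rob_ref_freq, 1) == 100 &&
      r$rob_coverage >= min_cov_rob
  }
  ok
}

# scan-and-split restriction digest oracle (independent of gregexpr)
oracle_digest <- function(seq, site, cut_offset) {
  n <- nchar(seq)
  w <- nchar(site)
  cuts <- integer(0)
  for (i in seq_len(max(0L, n - w + 1L))) {
    if (substr(seq, i, i + w - 1L) == site) {
      cut <- i + cut_offset - 1L           # last base of the 5' fragment
      if (cut >= 1L && cut < n) cuts <- c(cuts, cut)
    }
  }
  diff(c(0L, sort(unique(cuts)), n))
}

# Dirichlet-multinomial predictive genotype probability by numerical
# integration over the allele-frequency posterior (k = 2 or 3)
oracle_predictive <- function(genotype, counts, k, tau = 1 / k) {
  alleles <- names(counts)
  stopifnot(length(alleles) == k)
  n <- unname(counts)
  gfun <- function(p) {
    # genotype probability at fixed allele frequencies p (named)
    a <- genotype[1]
    b <- genotype[2]
    if (a == b) p[[a]]^2 else 2 * p[[a]] * p[[b]]
  }
  if (k == 2) {
    dens <- function(x) stats::dbeta(x, n[1] + tau, n[2] + tau)
    stats::integrate(function(x) {
      vapply(x, function(xi) {
        p <- stats::setNames(c(xi, 1 - xi), alleles)
        gfun(p) * dens(xi)
      }, numeric(1))
    }, 0, 1, rel.tol = 1e-10)$value
  } else if (k == 3) {
    ddir <- function(p, a) {
      exp(lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(p)))
    }
    inner <- function(x) {
      vapply(x, function(xi) {
        stats::integrate(function(y) {
          vapply(y, function(yi) {
            if (xi + yi >= 1) return(0)
            p <- stats::setNames(c(xi, yi, 1 - xi - yi), alleles)
            gfun(p) * ddir(p, n + tau)
          }, numeric(1))
        }, 0, 1 - xi, rel.tol = 1e-8)$value
      }, numeric(1))
    }
    stats::integrate(inner, 0, 1, rel.tol = 1e-8)$value
  } else {
    stop("oracle supports k <= 3")
  }
}

# quick construction of a reference panel from per-locus genotype vectors
tiny_panel <- function(group, ...) {
  cols <- list(...)
  n <- length(cols[[1]])
  df <- data.frame(sample_id = sprintf("%s_%d", group, seq_len(n)),
                   group = group, cols, stringsAsFactors = FALSE)
  reference_panel(df, group = group)
}

# one-row query genotype data.frame
query_row <- function(sample_id = "q", group = "unknown", ...) {
  data.frame(sample_id = sample_id, group = group, ...,
             stringsAsFactors = FALSE)
}

# the six panel loci in order
LOCI <- c("QP_miSeq14a_SNP1", "QP_miSeq14a_SNP2", "QP_miSeq32",
          "QP_miSeq36", "QP_miSeq38_SNP1", "QP_miSeq38_SNP2")

# fully species-modal six-locus genotypes
modal_petraea_query <- function(id = "QUPET_modal") {
  q <- query_row(id, "unknown",
                 QP_miSeq14a_SNP1 = "C/C", QP_miSeq14a_SNP2 = "T/T",
                 QP_miSeq32 = "193/193", QP_miSeq36 = "C/C",
                 QP_miSeq38_SNP1 = "A/A", QP_miSeq38_SNP2 = "C/C")
  q
}

modal_robur_query <- function(id = "QUROB_modal") {
  query_row(id, "unknown",
            QP_miSeq14a_SNP1 = "T/T", QP_miSeq14a_SNP2 = "C/C",
            QP_miSeq32 = "188/188", QP_miSeq36 = "T/T",
            QP_miSeq38_SNP1 = "G/G", QP_miSeq38_SNP2 = "A/A")
}
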
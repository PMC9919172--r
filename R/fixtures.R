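# Synthetic-data generators. These emulate the downstream products of the
# two oak Pool-seq experiments: marker-region template sequences, merged
# pool variant tables with planted truth, and reference genotype panels
# with the published genotype-class frequencies. Everything is seeded and
# reproducible.

# ---- marker-region templates ------------------------------------------------

# Bases of the robur-allele amplicon that are fixed by design (enzyme sites
# and diagnostic positions); everything else is seeded-random filler.
region_fixed_bases <- function(marker) {
  switch(marker$marker_id,
    QP_miSeq14a = c("81" = "G", "82" = "A", "83" = "T", "84" = "T",
                    "86" = "C"),
    QP_miSeq32 = character(0),
    QP_miSeq36 = c("86" = "T", "87" = "T", "88" = "A", "89" = "A"),
    QP_miSeq38 = c("90" = "G", "120" = "A"),
    character(0)
  )
}

# enzyme-site count each allele's amplicon must show (NULL = no constraint)
region_site_constraint <- function(marker) {
  switch(marker$marker_id,
    QP_miSeq14a = list(site = "GATC", robur = 0L, petraea = 1L),
    QP_miSeq36 = list(site = "TTAA", robur = 1L, petraea = 0L),
    NULL
  )
}

petraea_amplicon <- function(marker, amp_rob) {
  loci <- marker$loci[order(-marker$loci$amplicon_offset), , drop = FALSE]
  amp <- amp_rob
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    if (l$ref_allele == "-" || l$alt_allele == "-") {
      amp <- apply_variant(amp, l$amplicon_offset, l$ref_allele,
                           l$alt_allele)
    } else {
      amp <- apply_variant(amp, l$amplicon_offset, l$allele_rob,
                           l$allele_pet)
    }
  }
  amp
}

primer_layout_ok <- function(seq, marker) {
  count_matches(seq, marker$fwd) == 1L &&
    count_matches(seq, revcomp(marker$rev)) == 1L &&
    count_matches(seq, marker$rev) == 0L &&
    count_matches(seq, revcomp(marker$fwd)) == 0L &&
    regexpr(marker$fwd, seq, fixed = TRUE)[1] <
      regexpr(revcomp(marker$rev), seq, fixed = TRUE)[1]
}

build_region_templates <- function(marker, flank, max_tries = 500L) {
  L <- marker$expected_len[["robur"]]
  nf <- nchar(marker$fwd)
  nr <- nchar(marker$rev)
  fixed <- region_fixed_bases(marker)
  cons <- region_site_constraint(marker)
  for (try in seq_len(max_tries)) {
    amp <- paste0(marker$fwd, rand_dna(L - nf - nr), revcomp(marker$rev))
    for (off in names(fixed)) {
      substr(amp, as.integer(off), as.integer(off)) <- fixed[[off]]
    }
    amp_pet <- petraea_amplicon(marker, amp)
    fl <- rand_dna(flank)
    fr <- rand_dna(flank)
    tpl_rob <- paste0(fl, amp, fr)
    tpl_pet <- paste0(fl, amp_pet, fr)
    ok <- primer_layout_ok(tpl_rob, marker) &&
      primer_layout_ok(tpl_pet, marker)
    if (ok && !is.null(cons)) {
      ok <- count_matches(amp, cons$site) == cons$robur &&
        count_matches(amp_pet, cons$site) == cons$petraea
    }
    if (ok) {
      return(list(amp_rob = amp, amp_pet = amp_pet,
                  tpl_rob = tpl_rob, tpl_pet = tpl_pet,
                  amp_start = flank + 1L))
    }
  }
  stopf("marker %s: could not place filler sequence in %d tries",
        marker$marker_id, max_tries)
}

#' Generate marker-region template sequences
#'
#' Builds, for every region of the marker panel, a pair of template
#' sequences (robur and petraea allele) that embed the exact primer
#' sequences, carry the diagnostic variants at fixed amplicon offsets and
#' reproduce the published amplicon and restriction-fragment lengths. For
#' the InDel region an additional `caucasus-petraea` template carrying the
#' short (188 bp) allele on a petraea background is produced. Filler
#' sequence is seeded-random and screened against spurious primer or
#' enzyme sites; the QP_miSeq36 template is stored on the opposite strand
#' because its primers bind the reverse complement of the reference.
#'
#' @param seed RNG seed.
#' @param panel A `marker_panel`.
#' @param flank Number of random bases flanking each amplicon.
#' @return An object of class `marker_templates`: list with `records`
#'   (named `marker|allele` entries holding `sequence`, `strand`,
#'   `amplicon_span` and amplicon-local `variant_offsets`), `manifest`
#'   (one data.frame row per template, the layout sidecar) and `panel`.
#' @export
#' @examples
#' tpl <- make_marker_templates(seed = 1)
#' tpl$manifest[, c("marker_id", "allele", "length")]
make_marker_templates <- function(seed = 1L, panel = oak_marker_panel(),
                                  flank = 30L) {
  with_seed_if(seed)
  records <- list()
  for (m in panel) {
    built <- build_region_templates(m, flank)
    span <- c(built$amp_start, built$amp_start + nchar(built$amp_rob) - 1L)
    span_pet <- c(built$amp_start,
                  built$amp_start + nchar(built$amp_pet) - 1L)
    orient <- function(s) if (m$strand == "-") revcomp(s) else s
    rec <- function(allele, tpl, sp) {
      list(marker_id = m$marker_id, allele = allele,
           sequence = orient(tpl), strand = m$strand,
           amplicon_span = sp, variant_offsets = m$loci$amplicon_offset)
    }
    records[[paste0(m$marker_id, "|robur")]] <-
      rec("robur", built$tpl_rob, span)
    records[[paste0(m$marker_id, "|petraea")]] <-
      rec("petraea", built$tpl_pet, span_pet)
    if (m$marker_id == "QP_miSeq32") {
      # Caucasus-origin petraea carry the short (robur-length) allele
      records[["QP_miSeq32|caucasus-petraea"]] <-
        rec("caucasus-petraea", built$tpl_rob, span)
    }
  }
  manifest <- do.call(rbind, lapply(records, function(r) {
    data.frame(marker_id = r$marker_id, allele = r$allele,
               strand = r$strand, length = nchar(r$sequence),
               amp_start = r$amplicon_span[1], amp_end = r$amplicon_span[2],
               variant_offsets = paste(r$variant_offsets, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  structure(list(records = records, manifest = manifest, panel = panel),
            class = "marker_templates")
}

#' @export
print.marker_templates <- function(x, ...) {
  cat(sprintf("<marker_templates> %d templates over %d regions\n",
              length(x$records), length(x$panel)))
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' Look up one template sequence
#'
#' @param templates A `marker_templates` object.
#' @param marker_id Region id, e.g. `"QP_miSeq32"`.
#' @param allele `"robur"`, `"petraea"` or `"caucasus-petraea"`.
#' @return Character scalar.
#' @export
template_sequence <- function(templates, marker_id, allele) {
  key <- paste0(marker_id, "|", allele)
  rec <- templates$records[[key]]
  if (is.null(rec)) stopf("no template '%s'", key)
  rec$sequence
}

#' Write templates to FASTA
#'
#' Record ids follow the `marker|allele` convention.
#'
#' @param templates A `marker_templates` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_templates_fasta <- function(templates, path) {
  seqs <- vapply(templates$records, `[[`, character(1), "sequence")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(templates$records)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read templates from FASTA
#'
#' Reads a FASTA written by [write_templates_fasta()] back into a plain
#' named character vector of sequences keyed by `marker|allele`.
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_templates_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

# ---- CDS fixture for the coding-effect annotation ---------------------------

#' Synthetic CDS fixture for the Chr9 marker region
#'
#' Generates a synthetic coding sequence in which the two Chr9 diagnostic
#' SNPs fall into one codon, on the minus strand of the genomic fragment,
#' such that the robur alleles encode alanine and the petraea alleles
#' threonine at protein position 125 (the annotated effect of this marker
#' region in the detoxification 56-like gene). Only the variant-bearing
#' codon is constrained; the rest of the CDS is seeded-random sense
#' codons.
#'
#' @param seed RNG seed.
#' @return List with `fragment` (genomic strand, CDS on the minus
#'   strand), `variants` (data.frame of the two substitutions in fragment
#'   coordinates), `cds_strand` (`"-"`) and `gene`.
#' @export
#' @examples
#' fx <- make_cds_fixture(seed = 1)
#' coding_effect(fx$fragment, fx$variants, fx$cds_strand)
make_cds_fixture <- function(seed = 1L) {
  with_seed_if(seed)
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, stops)
  n_codons <- 135L
  codons <- sample(sense, n_codons, replace = TRUE)
  codons[1] <- "ATG"
  codons[125] <- "GCA"          # alanine; petraea alleles turn it into ACG
  codons[n_codons] <- "TAA"
  cds <- paste(codons, collapse = "")
  fragment <- revcomp(cds)
  # CDS position 373..375 maps to fragment offsets 33..31 on the minus
  # strand; the two SNPs sit two bases apart, as on Chr9.
  variants <- data.frame(
    locus = c("QP_miSeq14a_SNP1", "QP_miSeq14a_SNP2"),
    offset = c(31L, 33L),
    ref_allele = c("T", "C"),
    alt_allele = c("C", "T"),
    stringsAsFactors = FALSE
  )
  stopifnot(substr(fragment, 31, 31) == "T",
            substr(fragment, 33, 33) == "C")
  list(fragment = fragment, variants = variants, cds_strand = "-",
       gene = "LOC115972447 (protein detoxification 56-like)")
}

# ---- pool variant tables with planted truth ---------------------------------

rpois_at_least <- function(n, lambda, minimum) {
  x <- stats::rpois(n, lambda)
  while (any(bad <- x < minimum)) {
    x[bad] <- stats::rpois(sum(bad), lambda)
  }
  x
}

random_alleles <- function(vtype) {
  bases <- c("A", "C", "G", "T")
  switch(vtype,
    SNV = {
      r <- sample(bases, 1)
      c(r, sample(setdiff(bases, r), 1))
    },
    MNV = {
      r <- paste(sample(bases, 2, replace = TRUE), collapse = "")
      a <- r
      while (a == r) a <- paste(sample(bases, 2, TRUE), collapse = "")
      c(r, a)
    },
    InDel = {
      ins <- rand_dna(sample(1:5, 1))
      if (stats::runif(1) < 0.5) c("-", ins) else c(ins, "-")
    }
  )
}

#' Generate a pair of pool variant tables with planted truth
#'
#' Emulates the merged-variant input of the discovery stage: a petraea
#' pool variant table (about 29X), a robur pool variant table and a robur
#' per-position coverage track (about 19X). `n_diagnostic` variants are
#' planted to survive the full fixed-difference filter cascade (petraea
#' alternative allele frequency 100% at coverage >= 13; robur reference
#' allele frequency 100% at coverage >= 5); `n_background` variants each
#' violate exactly one cascade stage, cycling through the four failure
#' modes (`alt_freq`, `pet_coverage`, `rob_no_coverage`, `rob_ref_freq`),
#' and the violated stage is recorded in the truth set.
#'
#' @param seed RNG seed.
#' @param n_diagnostic Number of planted diagnostic variants (>= 0).
#' @param n_background Number of planted background variants (>= 0);
#'   `n_diagnostic + n_background` must be at least 1.
#' @param cov_pet_mean,cov_rob_mean Poisson means of the per-position
#'   sequencing depths of the two pools (defaults 29 and 19).
#' @return List with `pet` and `rob` (pool variant data.frames with
#'   columns `reference`, `position`, `vtype`, `ref_allele`,
#'   `alt_allele`, `alt_count`, `coverage`, `alt_freq`), `rob_coverage`
#'   (data.frame `reference`, `position`, `depth`) and `truth` (class
#'   `truth_set`, with `diagnostic` and `background` key tables).
#' @export
make_pool_variant_tables <- function(seed = 1L, n_diagnostic = 6L,
                                     n_background = 24L,
                                     cov_pet_mean = 29, cov_rob_mean = 19) {
  if (n_diagnostic < 0L || n_background < 0L) {
    stopf("variant counts must be non-negative")
  }
  if (n_diagnostic + n_background < 1L) {
    stopf("need at least one variant to generate")
  }
  with_seed_if(seed)
  n <- n_diagnostic + n_background
  reference <- sample(paste0("Chr", 1:12), n, replace = TRUE)
  position <- sample.int(5000000L, n)        # globally unique
  vtype <- sample(c("SNV", "MNV", "InDel"), n, replace = TRUE,
                  prob = c(0.7, 0.15, 0.15))
  alle <- t(vapply(vtype, random_alleles, character(2)))
  stage <- c(rep(NA_character_, n_diagnostic),
             rep(c("alt_freq", "pet_coverage", "rob_no_coverage",
                   "rob_ref_freq"), length.out = n_background))

  coverage <- rpois_at_least(n, cov_pet_mean, 13L)
  coverage[stage %in% "pet_coverage"] <-
    sample(1:12, sum(stage %in% "pet_coverage"), replace = TRUE)
  alt_count <- coverage
  low <- which(stage %in% "alt_freq")
  alt_count[low] <- vapply(coverage[low], function(cv) {
    sample(seq(max(1L, ceiling(cv / 2)), cv - 1L), 1L)
  }, numeric(1))
  pet <- data.frame(reference = reference, position = position,
                    vtype = vtype, ref_allele = alle[, 1],
                    alt_allele = alle[, 2], alt_count = alt_count,
                    coverage = coverage,
                    alt_freq = round(100 * alt_count / coverage, 1),
                    stringsAsFactors = FALSE)

  has_depth <- !(stage %in% "rob_no_coverage")
  depth <- rpois_at_least(n, cov_rob_mean, 5L)
  rob_coverage <- data.frame(reference = reference[has_depth],
                             position = position[has_depth],
                             depth = depth[has_depth],
                             stringsAsFactors = FALSE)

  notref <- which(stage %in% "rob_ref_freq")
  rob <- pet[notref, , drop = FALSE]
  if (length(notref)) {
    rob$coverage <- depth[notref]
    rob$alt_count <- vapply(rob$coverage, function(cv) {
      sample(seq_len(max(1L, floor(cv / 2))), 1L)
    }, numeric(1))
    rob$alt_freq <- round(100 * rob$alt_count / rob$coverage, 1)
  }
  rownames(rob) <- NULL

  key_cols <- c("reference", "position", "ref_allele", "alt_allele")
  diag_idx <- seq_len(n_diagnostic)
  bg_idx <- setdiff(seq_len(n), diag_idx)
  background <- pet[bg_idx, key_cols, drop = FALSE]
  background$stage <- stage[bg_idx]
  truth <- structure(
    list(diagnostic = pet[diag_idx, key_cols, drop = FALSE],
         background = background),
    class = "truth_set"
  )
  rownames(truth$diagnostic) <- rownames(truth$background) <- NULL

  ord <- sample.int(n)
  pet <- pet[ord, , drop = FALSE]
  rownames(pet) <- NULL
  list(pet = pet, rob = rob, rob_coverage = rob_coverage, truth = truth)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d diagnostic, %d background\n",
              nrow(x$diagnostic), nrow(x$background)))
  if (nrow(x$background)) print(table(x$background$stage))
  invisible(x)
}

# ---- reference genotype panels ----------------------------------------------

#' Published genotype-class frequencies of the reference panels
#'
#' Per-region genotype-class percentages observed in the validated
#' reference sets (39 robur / 45 petraea individuals; 77 each at the
#' InDel region). Classes at the two-SNP regions are joint (`"TT|CC"`
#' means SNP1 `T/T` and SNP2 `C/C`), reflecting that the paired SNPs were
#' always co-typed.
#'
#' @return Nested named list: group -> region -> named percentage vector.
#' @export
oak_reference_freqs <- function() {
  list(
    QUROB = list(
      QP_miSeq14a = c("TT|CC" = 100),
      QP_miSeq32 = c("188/188" = 96, "188/193" = 4),
      QP_miSeq36 = c("TT" = 85, "CT" = 13, "CC" = 2),
      QP_miSeq38 = c("GG|AA" = 92, "GA|AC" = 8)
    ),
    QUPET = list(
      QP_miSeq14a = c("CC|TT" = 84, "CT|TC" = 16),
      QP_miSeq32 = c("193/193" = 64, "188/188" = 18, "188/193" = 18),
      QP_miSeq36 = c("CC" = 81, "CT" = 15, "TT" = 4),
      QP_miSeq38 = c("AA|CC" = 93, "GA|AC" = 7)
    )
  )
}

#' Configuration of the synthetic reference panels
#'
#' @param n_robur,n_petraea,n_hybrid Panel sizes (defaults 39, 45, 20).
#' @param n_indel_extra Named vector: extra individuals per species typed
#'   only at the InDel region, bringing its totals to 77/77.
#' @param genotype_freqs Genotype-class percentages, see
#'   [oak_reference_freqs()].
#' @param seed RNG seed.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_robur = 39L, n_petraea = 45L, n_hybrid = 20L,
                         n_indel_extra = c(QUROB = 38L, QUPET = 32L),
                         genotype_freqs = oak_reference_freqs(),
                         seed = 1L) {
  if (min(n_robur, n_petraea, n_hybrid) < 1L) {
    stopf("panel sizes must be positive")
  }
  for (grp in names(genotype_freqs)) {
    for (region in names(genotype_freqs[[grp]])) {
      pct <- genotype_freqs[[grp]][[region]]
      if (abs(sum(pct) - 100) >= 1 - 1e-9) {
        stopf("%s/%s: genotype-class percentages sum to %g, not 100",
              grp, region, sum(pct))
      }
    }
  }
  structure(list(n_robur = n_robur, n_petraea = n_petraea,
                 n_hybrid = n_hybrid, n_indel_extra = n_indel_extra,
                 genotype_freqs = genotype_freqs, seed = seed),
            class = "panel_config")
}

# integer class counts whose realized percentages stay within +/-1 point
realize_counts <- function(pct, n, label) {
  counts <- largest_remainder(pct, n)
  dev <- abs(100 * counts / n - pct)
  if (any(dev > 1 + 1e-9)) {
    stopf("%s: percentages c(%s) cannot be realized as %d integer counts within +/-1%%",
          label, paste(pct, collapse = ", "), n)
  }
  counts
}

# expand a joint class label like "CT|TC" or "188/193" into per-locus
# canonical genotype strings for the region's loci
class_to_genotypes <- function(label, marker) {
  parts <- strsplit(label, "|", fixed = TRUE)[[1]]
  if (length(parts) != nrow(marker$loci)) {
    stopf("class '%s' does not match the %d loci of %s", label,
          nrow(marker$loci), marker$marker_id)
  }
  vapply(parts, function(p) {
    if (grepl("/", p, fixed = TRUE)) {
      a <- geno_alleles(p)
    } else {
      a <- strsplit(p, "")[[1]]
      if (length(a) != 2L) stopf("cannot parse genotype class '%s'", p)
    }
    geno_str(a[1], a[2])
  }, character(1), USE.NAMES = FALSE)
}

#' Reconstruct the reference genotype panels
#'
#' Builds the three reference panels used for assignment: the two species
#' panels are reconstructed deterministically from the published
#' genotype-class percentages (largest-remainder apportionment into
#' integer counts, then a seeded shuffle of class labels across
#' individuals within each region), and the hybrid panel is a set of
#' seeded F1 simulants drawn from the species panels' posterior-mean
#' allele frequencies. Extra individuals typed only at the InDel region
#' extend that region's totals (77/77 by default).
#'
#' @param cfg A [panel_config()].
#' @return Named list of class `reference_panel_set` with elements
#'   `QUROB`, `QUPET` and `Hybrid`, each a [reference_panel()].
#' @export
#' @examples
#' panels <- make_reference_panels(panel_config(seed = 1))
#' summarize_panel(panels$QUPET)
make_reference_panels <- function(cfg = panel_config()) {
  with_seed_if(cfg$seed)
  panel <- oak_marker_panel()
  loci <- panel_locus_names(panel)

  build_species <- function(group, n_core) {
    n_extra <- unname(cfg$n_indel_extra[group] %||% 0L)
    if (is.na(n_extra)) n_extra <- 0L
    n_all <- n_core + n_extra
    g <- as.data.frame(matrix(NA_character_, nrow = n_all,
                              ncol = length(loci)),
                       stringsAsFactors = FALSE)
    names(g) <- loci
    for (region in names(cfg$genotype_freqs[[group]])) {
      m <- panel[[region]]
      pct <- cfg$genotype_freqs[[group]][[region]]
      n_region <- if (region == "QP_miSeq32") n_all else n_core
      counts <- realize_counts(pct, n_region,
                               paste(group, region, sep = "/"))
      labels <- rep(names(pct), counts)
      labels <- sample(labels)                    # shuffle across members
      rows <- seq_len(n_region)
      for (i in rows) {
        g[i, m$loci$locus] <- class_to_genotypes(labels[i], m)
      }
    }
    g <- cbind(sample_id = sprintf("%s_%03d", group, seq_len(n_all)),
               group = group, g, stringsAsFactors = FALSE)
    reference_panel(g, group = group)
  }

  rob <- build_species("QUROB", cfg$n_robur)
  pet <- build_species("QUPET", cfg$n_petraea)

  hyb_rows <- do.call(rbind, lapply(seq_len(cfg$n_hybrid), function(i) {
    hybrid_draw(list(rob, pet), generation = "F1",
                sample_id = sprintf("HYB_%03d", i))
  }))
  hyb <- reference_panel(hyb_rows, group = "Hybrid")

  structure(list(QUROB = rob, QUPET = pet, Hybrid = hyb),
            class = "reference_panel_set")
}

#' @export
print.reference_panel_set <- function(x, ...) {
  cat("<reference_panel_set>\n")
  for (p in x) {
    cat(sprintf("  %-7s n=%d (%d fully typed at >=4 loci)\n", p$group,
                nrow(p$genotypes),
                sum(rowSums(!is.na(p$genotypes[p$loci])) >= 4)))
  }
  invisible(x)
}

# ---- hybrid simulation ------------------------------------------------------

# one simulated hybrid; uses the current RNG stream
hybrid_draw <- function(parent_panels, generation = "F1",
                        backcross_parent = 1L, sample_id = "HYB_1") {
  p1 <- parent_panels[[1]]
  p2 <- parent_panels[[2]]
  loci <- p1$loci
  draw_from <- function(panel, locus) {
    counts <- allele_counts(panel, locus)
    universe <- sort(unique(c(names(allele_counts(p1, locus)),
                              names(allele_counts(p2, locus)))),
                     method = "radix")
    if (!length(universe)) {
      stopf("parental panels are empty at locus %s", locus)
    }
    tau <- 1 / length(universe)
    n_a <- stats::setNames(rep(0, length(universe)), universe)
    n_a[names(counts)] <- counts
    p <- (n_a + tau) / (sum(n_a) + 1)
    sample(universe, 1L, prob = p)
  }
  f1_gamete <- function(locus) {
    parent <- if (stats::runif(1) < 0.5) p1 else p2
    draw_from(parent, locus)
  }
  geno <- vapply(loci, function(l) {
    if (!nrow_nonmissing(p1, l) || !nrow_nonmissing(p2, l)) {
      stopf("parental panels must be non-empty at every locus (%s)", l)
    }
    pair <- switch(generation,
      F1 = c(draw_from(p1, l), draw_from(p2, l)),
      backcross = c(draw_from(parent_panels[[backcross_parent]], l),
                    f1_gamete(l)),
      stopf("unknown hybrid generation '%s'", generation)
    )
    geno_str(pair[1], pair[2])
  }, character(1))
  out <- data.frame(sample_id = sample_id, group = "Hybrid",
                    t(geno), stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "group", loci)
  out
}

nrow_nonmissing <- function(panel, locus) {
  sum(!is_missing_geno(panel$genotypes[[locus]]))
}

#' Simulate a hybrid multilocus genotype
#'
#' Draws one hybrid individual from two parental reference panels. For an
#' F1, one allele per locus is drawn from each parent's posterior-mean
#' allele frequencies `(n_a + 1/k) / (n + 1)`; for a backcross, one
#' allele comes from the recurrent parent and the other from an F1 gamete
#' (a parent chosen at random, then an allele from its frequencies).
#' Draws are independent across loci.
#'
#' @param parent_panels List of two [reference_panel()] objects.
#' @param generation `"F1"` or `"backcross"`.
#' @param seed RNG seed (`NULL` uses the current stream).
#' @param backcross_parent Index (1 or 2) of the recurrent parent.
#' @param sample_id Sample id of the simulated individual.
#' @return One-row data.frame (`sample_id`, `group`, one genotype column
#'   per locus).
#' @export
simulate_hybrid <- function(parent_panels, generation = c("F1", "backcross"),
                            seed = NULL, backcross_parent = 1L,
                            sample_id = "HYB_1") {
  generation <- match.arg(generation)
  with_seed_if(seed)
  hybrid_draw(parent_panels, generation, backcross_parent, sample_id)
}

#' Simulate an individual from a panel's allele frequencies
#'
#' Draws two alleles per locus from the panel's posterior-mean allele
#' frequencies (Hardy-Weinberg draw). Used for exclusion-probability
#' simulants and self-consistency checks.
#'
#' @param panel A [reference_panel()].
#' @param seed RNG seed (`NULL` uses the current stream).
#' @param sample_id Sample id of the simulated individual.
#' @return One-row genotype data.frame.
#' @export
simulate_individual <- function(panel, seed = NULL, sample_id = "SIM_1") {
  with_seed_if(seed)
  geno <- vapply(panel$loci, function(l) {
    counts <- allele_counts(panel, l)
    universe <- names(counts)
    tau <- 1 / length(universe)
    p <- (counts + tau) / (sum(counts) + 1)
    pair <- sample(universe, 2L, replace = TRUE, prob = p)
    geno_str(pair[1], pair[2])
  }, character(1))
  out <- data.frame(sample_id = sample_id, group = panel$group, t(geno),
                    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "group", panel$loci)
  out
}
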
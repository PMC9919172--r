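# In-silico genotyping operators: PCR product extraction, variant editing,
# restriction digestion, genotype calling and coding-effect translation.

#' Extract the PCR product of a marker from a template sequence
#'
#' Performs exact-match in-silico PCR: the forward primer and the reverse
#' complement of the reverse primer are searched on both strands of the
#' template. The returned product includes both primer sequences and is
#' always oriented with the forward primer at its 5' end (templates stored
#' on the opposite strand are reverse-complemented first).
#'
#' @param template Template nucleotide sequence (character scalar).
#' @param marker A `marker_def`.
#' @return An object of class `amplicon`: list with `marker_id`,
#'   `sequence`, `template_span` (1-based inclusive, in template
#'   coordinates of the strand the primers were found on), `strand`
#'   (`"+"` or `"-"`) and `length`.
#' @export
#' @examples
#' tpl <- make_marker_templates(seed = 1)
#' amp <- extract_amplicon(template_sequence(tpl, "QP_miSeq32", "robur"),
#'                         oak_marker_panel()$QP_miSeq32)
#' amp$length  # 188
extract_amplicon <- function(template, marker) {
  products_on <- function(seq) {
    f <- gregexpr(marker$fwd, seq, fixed = TRUE)[[1]]
    r <- gregexpr(revcomp(marker$rev), seq, fixed = TRUE)[[1]]
    if (f[1] == -1L || r[1] == -1L) return(NULL)
    out <- list()
    for (fs in as.integer(f)) {
      for (rs in as.integer(r)) {
        re <- rs + nchar(revcomp(marker$rev)) - 1L
        if (rs > fs) out[[length(out) + 1L]] <- c(start = fs, end = re)
      }
    }
    out
  }
  plus <- products_on(template)
  minus <- products_on(revcomp(template))
  cand <- c(lapply(plus, function(x) list(span = x, strand = "+")),
            lapply(minus, function(x) list(span = x, strand = "-")))
  if (length(cand) == 0L) {
    stopf("marker %s: no in-silico PCR product on either strand",
          marker$marker_id)
  }
  if (length(cand) > 1L) {
    stopf("marker %s: %d candidate PCR products, expected exactly one",
          marker$marker_id, length(cand))
  }
  hit <- cand[[1]]
  subject <- if (hit$strand == "+") template else revcomp(template)
  seq <- substr(subject, hit$span[["start"]], hit$span[["end"]])
  structure(
    list(marker_id = marker$marker_id, sequence = seq,
         template_span = c(hit$span[["start"]], hit$span[["end"]]),
         strand = hit$strand, length = nchar(seq)),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s  %d bp  strand %s  span %d..%d\n",
              x$marker_id, x$length, x$strand,
              x$template_span[1], x$template_span[2]))
  invisible(x)
}

#' Apply a substitution, insertion or deletion to a sequence
#'
#' Alleles follow the dash convention: an insertion has `ref_allele = "-"`
#' and its bases are inserted beginning at `offset` (the base previously
#' at `offset` shifts right); a deletion has `alt_allele = "-"`.
#' Substitutions (SNV/MNV) replace in place and require the sequence to
#' carry `ref_allele` at `offset`.
#'
#' @param sequence Nucleotide sequence (character scalar).
#' @param offset 1-based position of the edit.
#' @param ref_allele Reference allele or `"-"` for an insertion.
#' @param alt_allele Alternative allele or `"-"` for a deletion.
#' @return The edited sequence. Its length is the input length plus
#'   `nchar(alt) - nchar(ref)` (with `"-"` counting zero).
#' @export
#' @examples
#' apply_variant("AATTAA", 3, "T", "G")       # "AAGTAA"
#' apply_variant("AATTAA", 3, "-", "CCC")     # "AACCCTTAA"
apply_variant <- function(sequence, offset, ref_allele, alt_allele) {
  n <- nchar(sequence)
  if (offset < 1L || offset > n + 1L) {
    stopf("variant offset %d outside sequence of length %d", offset, n)
  }
  if (identical(ref_allele, "-")) {        # insertion
    return(paste0(substr(sequence, 1L, offset - 1L), alt_allele,
                  substr(sequence, offset, n)))
  }
  found <- substr(sequence, offset, offset + nchar(ref_allele) - 1L)
  if (!identical(found, ref_allele)) {
    stopf("reference allele mismatch at offset %d: expected '%s', found '%s'",
          offset, ref_allele, found)
  }
  if (identical(alt_allele, "-")) {        # deletion
    return(paste0(substr(sequence, 1L, offset - 1L),
                  substr(sequence, offset + nchar(ref_allele), n)))
  }
  paste0(substr(sequence, 1L, offset - 1L), alt_allele,
         substr(sequence, offset + nchar(ref_allele), n))
}

#' Digest a sequence with a restriction enzyme
#'
#' Cuts at every occurrence of the recognition site, `cut_offset` bases
#' into the site; fragments are reported 5' to 3' and always sum to the
#' input length. A sequence without the site yields one full-length
#' fragment.
#'
#' @param sequence Nucleotide sequence (character scalar, non-empty).
#' @param enzyme An enzyme list as returned by [restriction_enzyme()].
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @export
#' @examples
#' digest("AAAGATCCCC", restriction_enzyme("MboI"))  # 3 7
digest <- function(sequence, enzyme) {
  if (!nzchar(sequence %||% "")) stopf("cannot digest an empty sequence")
  sites <- gregexpr(enzyme$site, sequence, fixed = TRUE)[[1]]
  n <- nchar(sequence)
  if (sites[1] == -1L) return(n)
  cuts <- as.integer(sites) + enzyme$cut_offset - 1L   # last base of 5' piece
  cuts <- cuts[cuts >= 1L & cuts < n]
  bounds <- c(0L, sort(unique(cuts)), n)
  as.integer(diff(bounds))
}

# -- genotype calling ---------------------------------------------------------

locus_genotype <- function(marker, which_allele) {
  # which_allele: character vector of 2 in {"rob","pet"} per haplotype
  vapply(seq_len(nrow(marker$loci)), function(i) {
    a <- ifelse(which_allele == "rob", marker$loci$allele_rob[i],
                marker$loci$allele_pet[i])
    geno_str(a[1], a[2])
  }, character(1))
}

caps_patterns <- function(marker) {
  rob <- sort(unique(marker$expected_fragments$robur))
  pet <- sort(unique(marker$expected_fragments$petraea))
  list(rob = rob, pet = pet, het = sort(unique(c(rob, pet))))
}

call_caps <- function(marker, lengths) {
  pat <- caps_patterns(marker)
  obs <- sort(unique(suppressWarnings(as.integer(unlist(lengths)))))
  if (anyNA(obs) || !length(obs)) {
    warnf("marker %s: non-numeric fragment observation; genotype set to missing",
          marker$marker_id)
    return(rep(NA_character_, nrow(marker$loci)))
  }
  hap <- if (identical(obs, pat$het) && !identical(pat$rob, pat$pet)) {
    c("rob", "pet")
  } else if (identical(obs, pat$rob)) {
    c("rob", "rob")
  } else if (identical(obs, pat$pet)) {
    c("pet", "pet")
  } else {
    warnf("marker %s: fragment pattern {%s} matches no defined allele; %s",
          marker$marker_id, paste(obs, collapse = ","),
          "genotype set to missing")
    return(rep(NA_character_, nrow(marker$loci)))
  }
  locus_genotype(marker, hap)
}

call_fragment_size <- function(marker, lengths) {
  lens <- suppressWarnings(as.integer(unlist(lengths)))
  if (anyNA(lens) || !length(lens)) {
    warnf("marker %s: non-numeric length observation; genotype set to missing",
          marker$marker_id)
    return(NA_character_)
  }
  if (length(lens) == 1L) lens <- rep(lens, 2L)
  if (length(lens) != 2L) {
    warnf("marker %s: expected 1 or 2 amplicon lengths, got %d",
          marker$marker_id, length(lens))
    return(NA_character_)
  }
  known <- unlist(marker$expected_fragments, use.names = FALSE)
  if (!all(lens %in% known)) {
    warnf("marker %s: amplicon length(s) {%s} match no defined allele",
          marker$marker_id, paste(sort(unique(lens)), collapse = ","))
    return(NA_character_)
  }
  geno_str(as.character(lens[1]), as.character(lens[2]))
}

call_sanger <- function(marker, bases) {
  bases <- as.list(bases)
  iupac <- Biostrings::IUPAC_CODE_MAP
  vapply(seq_len(nrow(marker$loci)), function(i) {
    l <- marker$loci[i, ]
    b <- bases[[l$locus]]
    if (is.null(b) && i <= length(bases)) b <- bases[[i]]
    b <- toupper(b %||% NA_character_)
    if (is.na(b)) return(NA_character_)
    expand <- if (b %in% names(iupac)) strsplit(iupac[[b]], "")[[1]] else
      character(0)
    both <- sort(c(l$allele_rob, l$allele_pet), method = "radix")
    if (identical(b, l$allele_rob)) {
      geno_str(l$allele_rob, l$allele_rob)
    } else if (identical(b, l$allele_pet)) {
      geno_str(l$allele_pet, l$allele_pet)
    } else if (length(expand) == 2L && identical(sort(expand), both)) {
      geno_str(both[1], both[2])
    } else {
      warnf("locus %s: base call '%s' matches no defined allele", l$locus, b)
      NA_character_
    }
  }, character(1))
}

#' Call the genotype of one marker region from an observation
#'
#' Maps a raw genotyping observation onto the marker's variant loci:
#'
#' * `caps` markers take the set of fragment lengths seen after
#'   restriction digestion; the union of both alleles' patterns (partial
#'   digest) is read as a heterozygote.
#' * `fragment_size` markers take one or two amplicon lengths; the
#'   lengths themselves are the allele labels (e.g. `{188, 193}` is the
#'   heterozygote `188/193`).
#' * `sanger` markers take named base calls at the variant offsets; IUPAC
#'   two-base ambiguity codes are read as heterozygotes (`Y` at a C/T
#'   locus gives `C/T`).
#' * `insilico` observations are two haplotype sequences containing the
#'   marker region; the appropriate physical observation is derived
#'   (digestion, sizing or base reading) and then called as above.
#'
#' Observations consistent with no defined allele give a missing genotype
#' with a warning, never an error.
#'
#' @param marker A `marker_def`.
#' @param observed The observation (see above).
#' @param mode Observation mode; defaults to the marker's method.
#' @return A data.frame with columns `locus` and `genotype`
#'   (canonical `"A/B"` strings, `NA` when unreadable).
#' @export
#' @examples
#' m <- oak_marker_panel()$QP_miSeq14a
#' call_locus(m, c(187, 80, 107))$genotype  # heterozygote at both SNPs
call_locus <- function(marker, observed,
                       mode = c("auto", "caps", "fragment_size", "sanger",
                                "insilico")) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- marker$method
  if (mode == "insilico") {
    stopifnot(is.character(observed), length(observed) == 2L)
    return(call_locus_insilico(marker, observed))
  }
  sangerable <- all(nchar(marker$loci$allele_rob) == 1L &
                      nchar(marker$loci$allele_pet) == 1L)
  if (mode != marker$method && !(mode == "sanger" && sangerable)) {
    # every SNP marker can alternatively be read from Sanger traces
    stopf("marker %s is genotyped by '%s', not '%s'",
          marker$marker_id, marker$method, mode)
  }
  g <- switch(mode,
    caps = call_caps(marker, observed),
    fragment_size = call_fragment_size(marker, observed),
    sanger = call_sanger(marker, observed)
  )
  data.frame(locus = marker$loci$locus, genotype = g,
             stringsAsFactors = FALSE)
}

# Derive the physical observation from two haplotype sequences, then call.
call_locus_insilico <- function(marker, haplotypes) {
  amps <- lapply(haplotypes, function(h) extract_amplicon(h, marker)$sequence)
  if (marker$method == "caps") {
    lens <- unlist(lapply(amps, digest, enzyme = marker$enzyme))
    call_locus(marker, lens, mode = "caps")
  } else if (marker$method == "fragment_size") {
    call_locus(marker, vapply(amps, nchar, integer(1)),
               mode = "fragment_size")
  } else {
    # read the base of each haplotype at every variant offset; merge to an
    # IUPAC code as a Sanger trace of the diploid would show
    bases <- lapply(seq_len(nrow(marker$loci)), function(i) {
      off <- marker$loci$amplicon_offset[i]
      b <- vapply(amps, substr, character(1), off, off)
      u <- sort(unique(b))
      if (length(u) == 1L) u else
        names(Biostrings::IUPAC_CODE_MAP)[
          match(paste(u, collapse = ""), Biostrings::IUPAC_CODE_MAP)]
    })
    names(bases) <- marker$loci$locus
    call_locus(marker, bases, mode = "sanger")
  }
}

#' Translate the coding effect of variants inside a CDS
#'
#' Applies the variants to the supplied genomic fragment, extracts the
#' coding sequence (reverse-complementing when the CDS lies on the minus
#' strand of the fragment), translates both alleles with the standard
#' genetic code and reports the first differing residue.
#'
#' @param fragment Genomic nucleotide fragment carrying the CDS. When
#'   `cds_strand = "+"` the fragment itself is the CDS; for `"-"` its
#'   reverse complement is. Length must be divisible by 3.
#' @param variants data.frame with columns `offset` (1-based in the
#'   fragment), `ref_allele`, `alt_allele` (substitutions only).
#' @param cds_strand `"+"` or `"-"`.
#' @param gene Optional gene label carried through to the result.
#' @return An object of class `coding_effect`: list with `gene`,
#'   `protein_position`, `ref_aa`, `alt_aa` and `consequence`
#'   (`"missense"`, `"synonymous"` or `"other"` when a premature stop is
#'   introduced).
#' @export
coding_effect <- function(fragment, variants, cds_strand = c("+", "-"),
                          gene = NA_character_) {
  cds_strand <- match.arg(cds_strand)
  if (nchar(fragment) %% 3L != 0L) {
    stopf("CDS length %d is not divisible by 3", nchar(fragment))
  }
  alt <- fragment
  for (i in seq_len(nrow(variants))) {
    alt <- apply_variant(alt, variants$offset[i], variants$ref_allele[i],
                         variants$alt_allele[i])
  }
  if (nchar(alt) != nchar(fragment)) {
    stopf("coding_effect handles substitutions only")
  }
  to_protein <- function(x) {
    if (cds_strand == "-") x <- revcomp(x)
    as.character(Biostrings::translate(Biostrings::DNAString(x)))
  }
  p_ref <- to_protein(fragment)
  p_alt <- to_protein(alt)
  ref_aa <- strsplit(p_ref, "")[[1]]
  alt_aa <- strsplit(p_alt, "")[[1]]
  diff <- which(ref_aa != alt_aa)
  if (!length(diff)) {
    eff <- list(gene = gene, protein_position = NA_integer_,
                ref_aa = NA_character_, alt_aa = NA_character_,
                consequence = "synonymous")
    return(structure(eff, class = "coding_effect"))
  }
  pos <- diff[1]
  new_stop <- any(alt_aa[diff] == "*" & ref_aa[diff] != "*")
  structure(
    list(gene = gene, protein_position = pos, ref_aa = ref_aa[pos],
         alt_aa = alt_aa[pos],
         consequence = if (new_stop) "other" else "missense"),
    class = "coding_effect"
  )
}

#' @export
print.coding_effect <- function(x, ...) {
  if (x$consequence == "synonymous") {
    cat("<coding_effect> synonymous\n")
  } else {
    cat(sprintf("<coding_effect> %s %s%d%s%s\n", x$consequence,
                x$ref_aa, x$protein_position, x$alt_aa,
                if (!is.na(x$gene)) paste0("  [", x$gene, "]") else ""))
  }
  invisible(x)
}
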
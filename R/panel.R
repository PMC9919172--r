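# The six-marker differentiation panel: four amplified regions, each with
# its primer pair, genotyping method, restriction enzyme (for CAPS markers)
# and the species-diagnostic variants it carries.

#' Restriction enzymes known to the package
#'
#' A minimal catalogue of type-II enzymes used by the CAPS markers of the
#' panel. `cut_offset` is the number of bases of the recognition site that
#' stay on the 5' fragment: MboI cuts ^GATC (offset 0), MseI cuts T^TAA
#' (offset 1).
#'
#' @param name Enzyme name, e.g. `"MboI"`.
#' @return A list with elements `name`, `site` and `cut_offset`.
#' @export
#' @examples
#' restriction_enzyme("MseI")$site
restriction_enzyme <- function(name) {
  cat <- list(
    MboI = list(name = "MboI", site = "GATC", cut_offset = 0L),
    MseI = list(name = "MseI", site = "TTAA", cut_offset = 1L),
    DpnII = list(name = "DpnII", site = "GATC", cut_offset = 0L)
  )
  if (!name %in% names(cat)) {
    stopf("unknown restriction enzyme '%s' (known: %s)",
          name, paste(names(cat), collapse = ", "))
  }
  cat[[name]]
}

new_marker_def <- function(marker_id, number, fwd, rev, method, enzyme,
                           loci, expected_len, expected_fragments,
                           strand = "+", gene = NA_character_) {
  stopifnot(nzchar(fwd), nzchar(rev))
  if (method == "caps" && is.null(enzyme)) {
    stopf("CAPS marker %s needs a restriction enzyme", marker_id)
  }
  structure(
    list(marker_id = marker_id, number = number, fwd = fwd, rev = rev,
         method = method, enzyme = enzyme, loci = loci,
         expected_len = expected_len,
         expected_fragments = expected_fragments,
         strand = strand, gene = gene),
    class = "marker_def"
  )
}

#' @export
print.marker_def <- function(x, ...) {
  enz <- if (is.null(x$enzyme)) "none" else
    sprintf("%s (%s)", x$enzyme$name, x$enzyme$site)
  cat(sprintf("<marker_def> %s  method=%s  enzyme=%s  strand=%s\n",
              x$marker_id, x$method, enz, x$strand))
  cat(sprintf("  amplicon: robur %d bp / petraea %d bp\n",
              x$expected_len[["robur"]], x$expected_len[["petraea"]]))
  print(x$loci, row.names = FALSE)
  invisible(x)
}

# Amplicon-local layout of each region. Published data fix the primer
# sequences, the variant alleles and the fragment sizes; where exactly the
# variants and enzyme sites sit inside the amplicon is a package design
# choice recorded here (and in the fixture manifest) so the printed
# fragment sizes are reproduced:
#   QP_miSeq14a: 187 bp; MboI site GATC at amplicon offset 81..84 in the
#     petraea allele (fragments 80 + 107); SNP1 at offset 84, SNP2 at 86.
#   QP_miSeq32: 188 bp (robur); 5-bp insertion GCTTC at offset 100 -> 193.
#   QP_miSeq36: 169 bp; MseI site TTAA at offset 86..89 in the robur allele
#     (fragments 86 + 83, cut T^TAA); SNP at offset 86. Primers bind the
#     reverse complement of the reference, so reference-orientation alleles
#     (A/G) are the complement of the marker-orientation alleles (T/C).
#   QP_miSeq38: 193 bp; SNP1 at offset 90, SNP2 at offset 120; Sanger read.

marker_locus_df <- function(locus, reference, position, ref_allele,
                            alt_allele, allele_rob, allele_pet, offset) {
  data.frame(locus = locus, reference = reference, position = position,
             ref_allele = ref_allele, alt_allele = alt_allele,
             allele_rob = allele_rob, allele_pet = allele_pet,
             amplicon_offset = offset, stringsAsFactors = FALSE)
}

#' The built-in oak differentiation marker panel
#'
#' Returns the definitions of the four amplified regions (six variants)
#' used to differentiate *Quercus robur* and *Q. petraea*: primer pairs,
#' genotyping method (CAPS digestion, amplicon sizing or Sanger reading),
#' restriction enzymes, per-allele amplicon lengths and expected fragment
#' patterns, and the diagnostic variants with their reference coordinates
#' and marker-orientation alleles.
#'
#' @return An object of class `marker_panel`: a named list of
#'   `marker_def` objects (`QP_miSeq14a`, `QP_miSeq32`, `QP_miSeq36`,
#'   `QP_miSeq38`).
#' @export
#' @examples
#' panel <- oak_marker_panel()
#' panel$QP_miSeq14a$expected_fragments$petraea
oak_marker_panel <- function() {
  p <- list(
    QP_miSeq14a = new_marker_def(
      marker_id = "QP_miSeq14a", number = 14L,
      fwd = "TGTTGACCAAAATGGATAAGAATT",
      rev = "GTTTGTCTGTCTTGAATGGCC",
      method = "caps", enzyme = restriction_enzyme("MboI"),
      loci = rbind(
        marker_locus_df("QP_miSeq14a_SNP1", "Chr9", 45479689L,
                        "T", "C", "T", "C", 84L),
        marker_locus_df("QP_miSeq14a_SNP2", "Chr9", 45479691L,
                        "C", "T", "C", "T", 86L)
      ),
      expected_len = c(robur = 187L, petraea = 187L),
      expected_fragments = list(robur = 187L, petraea = c(80L, 107L)),
      gene = "LOC115972447 (protein detoxification 56-like)"
    ),
    QP_miSeq32 = new_marker_def(
      marker_id = "QP_miSeq32", number = 32L,
      fwd = "TGAGGGGAAATCACAATTATGTC",
      rev = "TGATGTTCTGTTCTGATGAATGAC",
      method = "fragment_size", enzyme = NULL,
      loci = marker_locus_df("QP_miSeq32", "Chr7", 38644432L,
                             "-", "GCTTC", "188", "193", 100L),
      expected_len = c(robur = 188L, petraea = 193L),
      expected_fragments = list(robur = 188L, petraea = 193L),
      gene = "LOC115974824 (RRC1 isoform X1/X2)"
    ),
    QP_miSeq36 = new_marker_def(
      marker_id = "QP_miSeq36", number = 36L,
      fwd = "TCACTTGTTCTATTTGCAACATAT",
      rev = "TATTCTGTGTCTGAGTAGGTGATAC",
      method = "caps", enzyme = restriction_enzyme("MseI"),
      loci = marker_locus_df("QP_miSeq36", "Chr2", 31588494L,
                             "A", "G", "T", "C", 86L),
      expected_len = c(robur = 169L, petraea = 169L),
      expected_fragments = list(robur = c(86L, 83L), petraea = 169L),
      strand = "-",
      gene = "LOC115974879 (two-component response regulator ARR12-like)"
    ),
    QP_miSeq38 = new_marker_def(
      marker_id = "QP_miSeq38", number = 38L,
      fwd = "GTAAATGGTAATTGAAAAGGCAT",
      rev = "CCTGAAACTCTTGTTCAGAAGAT",
      method = "sanger", enzyme = NULL,
      loci = rbind(
        marker_locus_df("QP_miSeq38_SNP1", "scaffold492", 52257L,
                        "G", "A", "G", "A", 90L),
        marker_locus_df("QP_miSeq38_SNP2", "scaffold492", 52287L,
                        "A", "C", "A", "C", 120L)
      ),
      expected_len = c(robur = 193L, petraea = 193L),
      expected_fragments = list(robur = 193L, petraea = 193L),
      gene = "LOC115974869 (transcription initiation factor TFIID subunit 5)"
    )
  )
  structure(p, class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d regions, %d variant loci\n",
              length(x), nrow(panel_loci(x))))
  for (m in x) {
    cat(sprintf("  %-12s %-13s %3d bp (robur) / %3d bp (petraea)\n",
                m$marker_id, m$method,
                m$expected_len[["robur"]], m$expected_len[["petraea"]]))
  }
  invisible(x)
}

#' All variant loci of a marker panel as one table
#'
#' @param panel A `marker_panel`.
#' @return A data.frame with one row per variant locus, including the
#'   marker id and number each locus belongs to.
#' @export
panel_loci <- function(panel) {
  out <- do.call(rbind, lapply(panel, function(m) {
    cbind(marker_id = m$marker_id, number = m$number, m$loci,
          stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Names of the genotype columns used in genotype tables
#' @param panel A `marker_panel`.
#' @return Character vector of locus names in panel order.
#' @export
panel_locus_names <- function(panel = oak_marker_panel()) {
  panel_loci(panel)$locus
}

#' Write a marker panel definition file
#'
#' Serializes a `marker_panel` to a plain-text, tab-separated definition
#' format (one `marker` block per region; `locus` lines carry locus name,
#' reference, position, reference/alternative allele, marker-orientation
#' robur/petraea allele and amplicon offset).
#'
#' @param panel A `marker_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# oakdiff marker panel, format v1", con)
  for (m in panel) {
    writeLines(c(
      paste("marker", m$marker_id, sep = "\t"),
      paste("number", m$number, sep = "\t"),
      paste("method", m$method, sep = "\t"),
      paste("strand", m$strand, sep = "\t"),
      paste("fwd", m$fwd, sep = "\t"),
      paste("rev", m$rev, sep = "\t"),
      if (!is.null(m$enzyme)) paste("enzyme", m$enzyme$name, sep = "\t"),
      paste("expected_len",
            sprintf("robur=%d,petraea=%d", m$expected_len[["robur"]],
                    m$expected_len[["petraea"]]), sep = "\t"),
      paste("fragments",
            sprintf("robur=%s;petraea=%s",
                    paste(m$expected_fragments$robur, collapse = ","),
                    paste(m$expected_fragments$petraea, collapse = ",")),
            sep = "\t"),
      if (!is.na(m$gene)) paste("gene", m$gene, sep = "\t"),
      vapply(seq_len(nrow(m$loci)), function(i) {
        l <- m$loci[i, ]
        paste("locus", l$locus, l$reference, l$position, l$ref_allele,
              l$alt_allele, l$allele_rob, l$allele_pet, l$amplicon_offset,
              sep = "\t")
      }, character(1))
    ), con)
  }
  invisible(path)
}

#' Read a marker panel definition file
#'
#' Parses the format written by [write_marker_panel()].
#'
#' @param path Path to a panel definition file.
#' @return A `marker_panel`.
#' @export
read_marker_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(fields, `[[`, character(1), 1L)
  starts <- which(keys == "marker")
  if (!length(starts)) stopf("%s: no 'marker' records found", path)
  ends <- c(starts[-1] - 1L, length(lines))
  markers <- lapply(seq_along(starts), function(b) {
    blk <- fields[starts[b]:ends[b]]
    kv <- function(key) {
      hit <- which(vapply(blk, `[[`, character(1), 1L) == key)
      if (!length(hit)) return(NULL)
      blk[[hit[1]]][-1]
    }
    loci <- blk[vapply(blk, `[[`, character(1), 1L) == "locus"]
    loci_df <- do.call(rbind, lapply(loci, function(l) {
      if (length(l) != 9L) {
        stopf("%s: malformed locus line '%s'", path,
              paste(l, collapse = "\t"))
      }
      marker_locus_df(l[2], l[3], as.integer(l[4]), l[5], l[6], l[7],
                      l[8], as.integer(l[9]))
    }))
    el <- kv("expected_len")[1]
    el <- strsplit(strsplit(el, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
    expected_len <- vapply(el, function(x) as.integer(x[2]), integer(1))
    names(expected_len) <- vapply(el, `[[`, character(1), 1L)
    fr <- strsplit(kv("fragments")[1], ";", fixed = TRUE)[[1]]
    fr <- strsplit(fr, "=", fixed = TRUE)
    expected_fragments <- lapply(fr, function(x) {
      as.integer(strsplit(x[2], ",", fixed = TRUE)[[1]])
    })
    names(expected_fragments) <- vapply(fr, `[[`, character(1), 1L)
    enz <- kv("enzyme")
    new_marker_def(
      marker_id = kv("marker")[1],
      number = as.integer(kv("number")[1]),
      fwd = kv("fwd")[1], rev = kv("rev")[1],
      method = kv("method")[1],
      enzyme = if (is.null(enz)) NULL else restriction_enzyme(enz[1]),
      loci = loci_df, expected_len = expected_len,
      expected_fragments = expected_fragments,
      strand = kv("strand")[1],
      gene = (kv("gene") %||% NA_character_)[1]
    )
  })
  names(markers) <- vapply(markers, `[[`, character(1), "marker_id")
  structure(markers, class = "marker_panel")
}
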
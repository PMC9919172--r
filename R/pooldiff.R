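# Pool-seq fixed-difference discovery: variant table IO, merging the two
# pools' evidence, and the filter cascade that reduces candidates to fixed
# interspecific differences.

CLC_COLUMNS <- c("Reference", "Position", "Type", "Reference allele",
                 "Allele", "Count", "Coverage", "Frequency")

validate_pool_variants <- function(df, where = "variant table") {
  req <- c("reference", "position", "vtype", "ref_allele", "alt_allele",
           "alt_count", "coverage", "alt_freq")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stopf("%s: missing columns %s", where, paste(missing, collapse = ", "))
  }
  bad <- which(df$alt_count > df$coverage | df$position < 1 |
                 df$alt_freq < 0 | df$alt_freq > 100)
  if (length(bad)) {
    stopf("%s: inconsistent row %d (%s:%d count=%s coverage=%s freq=%s)",
          where, bad[1], df$reference[bad[1]], df$position[bad[1]],
          df$alt_count[bad[1]], df$coverage[bad[1]], df$alt_freq[bad[1]])
  }
  mnv <- df$vtype == "MNV" &
    (nchar(df$ref_allele) > 2 | nchar(df$alt_allele) > 2)
  if (any(mnv)) {
    stopf("%s: MNV alleles longer than 2 bases at row %d", where,
          which(mnv)[1])
  }
  df
}

infer_vtype <- function(ref, alt) {
  ifelse(ref == "-" | alt == "-", "InDel",
         ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "MNV"))
}

detect_dialect <- function(path) {
  head <- readLines(path, n = 50L)
  if (length(head) && grepl("^##fileformat=VCF", head[1])) return("vcf")
  head <- head[!grepl("^#", head)]          # skip provenance comments
  if (length(head) && grepl("Reference", head[1]) &&
        grepl("Frequency", head[1])) {
    return("clc_csv")
  }
  stopf("%s: line 1 matches no supported dialect (VCF v4 or CLC-style CSV)",
        path)
}

read_clc_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  missing <- setdiff(CLC_COLUMNS, names(df))
  if (length(missing)) {
    stopf("%s: CLC-style header lacks column(s) %s", path,
          paste(missing, collapse = ", "))
  }
  out <- data.frame(
    reference = as.character(df$Reference),
    position = suppressWarnings(as.integer(df$Position)),
    vtype = as.character(df$Type),
    ref_allele = as.character(df[["Reference allele"]]),
    alt_allele = as.character(df$Allele),
    alt_count = suppressWarnings(as.numeric(df$Count)),
    coverage = suppressWarnings(as.numeric(df$Coverage)),
    alt_freq = suppressWarnings(as.numeric(df$Frequency)),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$position) | is.na(out$coverage) |
                 is.na(out$alt_count))
  if (length(bad)) {
    stopf("%s: malformed row %d (line %d): non-numeric Position/Count/Coverage",
          path, bad[1], bad[1] + 1L)
  }
  norecalc <- !is.na(out$alt_freq)
  out$alt_freq[!norecalc] <-
    100 * out$alt_count[!norecalc] / out$coverage[!norecalc]
  out$alt_freq <- round(out$alt_freq, 1)
  out
}

# VCF anchor-base representation -> dash convention, left position + 1
normalize_vcf_alleles <- function(pos, ref, alt) {
  if (nchar(ref) == nchar(alt)) {
    return(list(position = pos, ref_allele = ref, alt_allele = alt,
                anchor = NA_character_))
  }
  if (substr(ref, 1, 1) != substr(alt, 1, 1)) {
    stopf("unsupported VCF allele pair %s/%s at position %d", ref, alt, pos)
  }
  if (nchar(ref) == 1L) {                       # insertion
    list(position = pos + 1L, ref_allele = "-",
         alt_allele = substr(alt, 2L, nchar(alt)), anchor = ref)
  } else if (nchar(alt) == 1L) {                # deletion
    list(position = pos + 1L,
         ref_allele = substr(ref, 2L, nchar(ref)), alt_allele = "-",
         anchor = alt)
  } else {
    stopf("unsupported complex VCF allele pair %s/%s at position %d",
          ref, alt, pos)
  }
}

read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  dp <- info_num("DP")
  ao <- info_num("AO")
  af <- info_num("AF")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      nv <- normalize_vcf_alleles(as.integer(fix[i, "POS"]),
                                  fix[i, "REF"], alt)
      cov <- dp[i]
      cnt <- ao[i]
      frq <- af[i]
      if (is.na(frq) && !is.na(cnt) && !is.na(cov)) frq <- cnt / cov
      if (is.na(cnt) && !is.na(frq) && !is.na(cov)) cnt <- round(frq * cov)
      if (is.na(cov) || is.na(cnt)) {
        stopf("%s: record %d lacks DP/AO coverage information", path, i)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        reference = fix[i, "CHROM"], position = nv$position,
        vtype = infer_vtype(nv$ref_allele, nv$alt_allele),
        ref_allele = nv$ref_allele, alt_allele = nv$alt_allele,
        alt_count = cnt, coverage = cov,
        alt_freq = round(100 * if (is.na(frq)) cnt / cov else frq, 1),
        anchor = nv$anchor, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(reference = character(0), position = integer(0),
                      vtype = character(0), ref_allele = character(0),
                      alt_allele = character(0), alt_count = numeric(0),
                      coverage = numeric(0), alt_freq = numeric(0),
                      anchor = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read a pool variant table
#'
#' Reads per-pool variant evidence from either a VCF v4 subset (INFO keys
#' `DP`, `AO`, `AF`; multi-allelic records are split, anchor-base InDels
#' normalized to the dash convention at position + 1) or a CLC-style CSV
#' (`Reference, Position, Type, Reference allele, Allele, Count,
#' Coverage, Frequency`). Frequencies are recomputed as
#' `100 * alt_count / coverage` when absent.
#'
#' @param path Input path.
#' @param dialect `"auto"` (header detection), `"vcf"` or `"clc_csv"`.
#' @return data.frame with one row per alternative allele and columns
#'   `reference`, `position`, `vtype`, `ref_allele`, `alt_allele`,
#'   `alt_count`, `coverage`, `alt_freq`.
#' @export
read_variant_table <- function(path, dialect = c("auto", "vcf", "clc_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (dialect == "auto") dialect <- detect_dialect(path)
  df <- switch(dialect, vcf = read_vcf_variants(path),
               clc_csv = read_clc_csv(path))
  validate_pool_variants(df, where = path)
}

#' Write a pool variant table
#'
#' Writes the CLC-style CSV dialect, or a minimal VCF v4.2 in which
#' dash-convention InDels are re-anchored (using the recorded anchor base
#' when the table came from a VCF, `N` otherwise) at position - 1.
#'
#' @param variants Pool variant data.frame.
#' @param path Output path.
#' @param dialect `"clc_csv"` or `"vcf"`.
#' @param header Optional provenance lines (written as `#`/`##` comments).
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path,
                                dialect = c("clc_csv", "vcf"),
                                header = NULL) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "clc_csv") {
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    out <- data.frame(variants$reference, variants$position, variants$vtype,
                      variants$ref_allele, variants$alt_allele,
                      variants$alt_count, variants$coverage,
                      variants$alt_freq, check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(out) <- CLC_COLUMNS
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##source=oakdiff", if (!is.null(header))
                   paste0(" ", paste(header, collapse = "; "))),
                 "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
                 "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternative allele observations\">",
                 "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele frequency\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    anchor <- if ("anchor" %in% names(variants)) variants$anchor else
      rep(NA_character_, nrow(variants))
    for (i in seq_len(nrow(variants))) {
      ref <- variants$ref_allele[i]
      alt <- variants$alt_allele[i]
      pos <- variants$position[i]
      if (ref == "-" || alt == "-") {
        a <- anchor[i]
        if (is.na(a)) a <- "N"
        pos <- pos - 1L
        if (ref == "-") {
          ref <- a
          alt <- paste0(a, alt)
        } else {
          alt <- a
          ref <- paste0(a, ref)
        }
      }
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AO=%d;AF=%.6f",
                         variants$reference[i], pos, ref, alt,
                         as.integer(variants$coverage[i]),
                         as.integer(variants$alt_count[i]),
                         variants$alt_freq[i] / 100), con)
    }
  }
  invisible(path)
}

#' Read / write a per-position coverage track
#'
#' Three-column TSV (`reference`, `position`, `depth`); `#` lines are
#' treated as comments.
#'
#' @param path File path.
#' @return data.frame with `reference`, `position`, `depth`.
#' @export
read_coverage_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("reference", "position", "depth")
  if (!all(need %in% names(df))) {
    stopf("%s: not a coverage track (expected columns %s)", path,
          paste(need, collapse = ", "))
  }
  df[need]
}

#' @rdname read_coverage_track
#' @param track Coverage data.frame.
#' @param header Optional provenance lines.
#' @export
write_coverage_track <- function(track, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(track, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

variant_key <- function(df) {
  paste(df$reference, df$position, df$ref_allele, df$alt_allele,
        sep = "\r")
}

#' Merge the two pools' variant evidence
#'
#' Joins the petraea-pool variant table with the robur pool on the key
#' `(reference, position, ref_allele, alt_allele)` and attaches robur
#' coverage and reference-allele frequency to every petraea variant. When
#' the robur pool called any alternative allele at the position, the
#' reference-allele frequency is `100 - sum(alt frequencies)`; otherwise
#' it is 100% wherever the coverage track shows depth > 0, and undefined
#' (with `rob_coverage = 0`) where the robur mapping has no coverage.
#'
#' @param pet Petraea pool variant data.frame.
#' @param rob Robur pool variant data.frame (may be empty/`NULL`).
#' @param rob_cov Robur coverage track data.frame (`reference`,
#'   `position`, `depth`); positions absent from it count as depth 0.
#' @return data.frame: the petraea columns plus `rob_coverage` and
#'   `rob_ref_freq` (`NA` when `rob_coverage` is 0).
#' @export
merge_pools <- function(pet, rob = NULL, rob_cov = NULL) {
  for (tab in list(pet = pet, rob = rob)) {
    if (is.null(tab) || !nrow(tab)) next
    dup <- duplicated(variant_key(tab))
    if (any(dup)) {
      d <- tab[which(dup)[1], ]
      stopf("duplicate variant key within one pool: %s:%d %s>%s",
            d$reference, d$position, d$ref_allele, d$alt_allele)
    }
  }
  if (!nrow(pet)) {
    out <- pet
    out$rob_coverage <- numeric(0)
    out$rob_ref_freq <- numeric(0)
    return(out)
  }
  pos_key <- function(df) paste(df$reference, df$position, sep = "\r")
  depth <- numeric(nrow(pet))
  if (!is.null(rob_cov) && nrow(rob_cov)) {
    idx <- match(pos_key(pet), pos_key(rob_cov))
    depth <- ifelse(is.na(idx), 0, rob_cov$depth[idx])
  }
  ref_freq <- ifelse(depth > 0, 100, NA_real_)
  if (!is.null(rob) && nrow(rob)) {
    alt_at_pos <- tapply(rob$alt_freq, pos_key(rob), sum)
    cov_at_pos <- tapply(rob$coverage, pos_key(rob), max)
    hit <- match(pos_key(pet), names(alt_at_pos))
    called <- !is.na(hit)
    ref_freq[called] <- round(100 - unname(alt_at_pos[hit[called]]), 1)
    depth[called] <- pmax(depth[called], unname(cov_at_pos[hit[called]]))
  }
  out <- pet
  out$rob_coverage <- as.numeric(depth)
  out$rob_ref_freq <- ifelse(out$rob_coverage > 0, ref_freq, NA_real_)
  rownames(out) <- NULL
  out
}

#' Filter thresholds of the fixed-difference cascade
#'
#' Defaults are the discovery thresholds of the oak study: minimum
#' coverage 13 in the petraea pool and 5 in the robur pool, and 100%
#' required alternative (petraea) / reference (robur) allele frequencies.
#'
#' @param min_cov_petraea,min_cov_robur Minimum read depths.
#' @param required_alt_freq,required_ref_freq Required percent
#'   frequencies (compared exactly after rounding to one decimal).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_cov_petraea = 13, min_cov_robur = 5,
                              required_alt_freq = 100,
                              required_ref_freq = 100) {
  stopifnot(min_cov_petraea >= 0, min_cov_robur >= 0,
            required_alt_freq >= 0, required_alt_freq <= 100,
            required_ref_freq >= 0, required_ref_freq <= 100)
  structure(list(min_cov_petraea = min_cov_petraea,
                 min_cov_robur = min_cov_robur,
                 required_alt_freq = required_alt_freq,
                 required_ref_freq = required_ref_freq),
            class = "filter_thresholds")
}

#' Apply the fixed-difference filter cascade
#'
#' Reduces merged pool variants to fixed interspecific differences in
#' four ordered stages: (1) keep variants whose petraea alternative
#' allele frequency equals the required frequency (default 100%, exact
#' after rounding to one decimal); (2) keep petraea coverage >=
#' `min_cov_petraea`; (3) remove variants without robur mapping coverage;
#' (4) keep variants with robur reference allele frequency equal to the
#' required frequency and robur coverage >= `min_cov_robur`.
#'
#' @param merged Output of [merge_pools()].
#' @param thresholds A [filter_thresholds()].
#' @return List of class `cascade_result` with `variants` (survivors),
#'   `removed` (the removed rows plus a `stage` column) and `report`
#'   (class `cascade_report`: named stage counts).
#' @export
apply_filter_cascade <- function(merged, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  stage <- rep(NA_character_, nrow(merged))
  alt_ok <- round(merged$alt_freq, 1) == round(thresholds$required_alt_freq, 1)
  stage[!alt_ok] <- "alt_freq"
  cov_ok <- merged$coverage >= thresholds$min_cov_petraea
  stage[is.na(stage) & !cov_ok] <- "pet_coverage"
  nocov <- merged$rob_coverage == 0
  stage[is.na(stage) & nocov] <- "rob_no_coverage"
  ref_ok <- !is.na(merged$rob_ref_freq) &
    round(merged$rob_ref_freq, 1) == round(thresholds$required_ref_freq, 1) &
    merged$rob_coverage >= thresholds$min_cov_robur
  stage[is.na(stage) & !ref_ok] <- "rob_ref_freq"

  n_in <- nrow(merged)
  n1 <- sum(alt_ok)
  n2 <- sum(alt_ok & cov_ok)
  n_nocov <- sum(stage %in% "rob_no_coverage")
  n4 <- sum(is.na(stage))
  report <- structure(
    c(input = n_in, alt_freq_pass = n1, pet_coverage_pass = n2,
      rob_no_coverage_removed = n_nocov, final_pass = n4),
    class = "cascade_report"
  )
  survivors <- merged[is.na(stage), , drop = FALSE]
  removed <- merged[!is.na(stage), , drop = FALSE]
  removed$stage <- stage[!is.na(stage)]
  rownames(survivors) <- rownames(removed) <- NULL
  structure(list(variants = survivors, removed = removed, report = report),
            class = "cascade_result")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  cat(sprintf("  input variants:                 %d\n", x[["input"]]))
  cat(sprintf("  alt frequency pass:             %d\n", x[["alt_freq_pass"]]))
  cat(sprintf("  petraea coverage pass:          %d\n",
              x[["pet_coverage_pass"]]))
  cat(sprintf("  removed (no robur coverage):    %d\n",
              x[["rob_no_coverage_removed"]]))
  cat(sprintf("  robur ref-freq/coverage pass:   %d\n", x[["final_pass"]]))
  invisible(x)
}

#' @export
print.cascade_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Serialize a cascade report
#'
#' @param report A `cascade_report`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param header Optional provenance lines (TSV only).
#' @return `path`, invisibly.
#' @export
write_cascade_report <- function(report, path, format = c("tsv", "json"),
                                 header = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(
      data.frame(stage = names(report), count = as.integer(report)),
      con, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(as.list(report), path, auto_unbox = TRUE)
  }
  invisible(path)
}
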
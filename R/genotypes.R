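# Multilocus genotype tables, reference panels and their summaries.
#
# A genotype table is a data.frame with columns `sample_id`, `group` and
# one column per variant locus holding canonical unordered genotype
# strings ("C/T", "188/193"); missing genotypes are NA (serialized ".").

#' Construct a reference panel from a genotype table
#'
#' @param genotypes data.frame with `sample_id`, `group` and one genotype
#'   column per locus.
#' @param group Group label (e.g. `"QUROB"`); defaults to the single
#'   value of the `group` column.
#' @param loci Locus column names; defaults to every column except
#'   `sample_id` and `group`.
#' @return An object of class `reference_panel`: list with `group`,
#'   `genotypes` and `loci`.
#' @export
reference_panel <- function(genotypes, group = NULL, loci = NULL) {
  stopifnot(is.data.frame(genotypes),
            all(c("sample_id", "group") %in% names(genotypes)))
  loci <- loci %||% setdiff(names(genotypes), c("sample_id", "group"))
  group <- group %||% unique(genotypes$group)
  if (length(group) != 1L) {
    stopf("reference panel must have a single group label, got: %s",
          paste(group, collapse = ", "))
  }
  for (l in loci) {
    g <- genotypes[[l]]
    bad <- !is_missing_geno(g) & !grepl("^[^/]+/[^/]+$", g)
    if (any(bad)) {
      stopf("locus %s: malformed genotype '%s' (sample %s)", l,
            g[which(bad)[1]], genotypes$sample_id[which(bad)[1]])
    }
    # canonicalize allele order
    idx <- which(!is_missing_geno(g))
    genotypes[[l]][idx] <- vapply(g[idx], function(x) {
      a <- geno_alleles(x)
      geno_str(a[1], a[2])
    }, character(1), USE.NAMES = FALSE)
  }
  structure(list(group = group, genotypes = genotypes, loci = loci),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %s: %d members, %d loci\n", x$group,
              nrow(x$genotypes), length(x$loci)))
  invisible(x)
}

#' Allele counts of a panel at one locus
#'
#' Counts every allele over the non-missing members (2 per member),
#' optionally leaving one sample out.
#'
#' @param panel A [reference_panel()].
#' @param locus Locus name.
#' @param exclude_sample Optional `sample_id` to leave out.
#' @return Named numeric vector of allele counts (alphabetical order).
#' @export
allele_counts <- function(panel, locus, exclude_sample = NULL) {
  g <- panel$genotypes[[locus]]
  if (is.null(g)) stopf("panel %s has no locus '%s'", panel$group, locus)
  keep <- !is_missing_geno(g)
  if (!is.null(exclude_sample)) {
    keep <- keep & panel$genotypes$sample_id != exclude_sample
  }
  alleles <- unlist(strsplit(g[keep], "/", fixed = TRUE))
  if (!length(alleles)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(alleles)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out[order(names(out), method = "radix")]
}

#' Summarize a panel as genotype-class percentages
#'
#' Tabulates, per locus, the observed genotype classes of the panel with
#' integer percentages (largest-remainder rounding, so percentages sum to
#' 100 per locus) -- the format of the published reference genotyping
#' table.
#'
#' @param panel A [reference_panel()].
#' @return data.frame with columns `locus`, `genotype`, `count`, `pct`
#'   and `n_typed`, classes ordered by decreasing count within locus.
#' @export
summarize_panel <- function(panel) {
  if (!nrow(panel$genotypes)) stopf("cannot summarize an empty panel")
  out <- lapply(panel$loci, function(l) {
    g <- panel$genotypes[[l]]
    g <- g[!is_missing_geno(g)]
    if (!length(g)) return(NULL)
    tab <- sort(table(g), decreasing = TRUE)
    data.frame(locus = l, genotype = names(tab),
               count = as.integer(tab),
               pct = percent_lr(as.integer(tab)),
               n_typed = length(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a genotype table to CSV
#'
#' Missing genotypes are serialized as `"."`. An optional provenance
#' header (lines starting `#`) is written before the column header.
#'
#' @param genotypes Genotype data.frame (or a [reference_panel()], whose
#'   table is used).
#' @param path Output path.
#' @param header Optional character vector of `#` header lines.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(genotypes, path, header = NULL) {
  if (inherits(genotypes, "reference_panel")) {
    genotypes <- genotypes$genotypes
  }
  out <- genotypes
  for (col in names(out)) out[[col]][is.na(out[[col]])] <- "."
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype table from CSV
#'
#' @param path CSV path as written by [write_genotype_csv()]; must have
#'   `sample_id` and `group` columns, `.` denotes a missing genotype.
#' @return Genotype data.frame.
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df))) {
    stopf("%s: not a genotype table (missing columns: %s)", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  for (col in setdiff(names(df), need)) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][df[[col]] %in% c(".", "")] <- NA_character_
  }
  df
}

#' Split a genotype table into reference panels by group
#'
#' @param genotypes Genotype data.frame.
#' @param groups Group labels to keep (default: all).
#' @return Named list of [reference_panel()] objects.
#' @export
panels_from_genotypes <- function(genotypes, groups = NULL) {
  groups <- groups %||% unique(genotypes$group)
  out <- lapply(groups, function(grp) {
    reference_panel(genotypes[genotypes$group == grp, , drop = FALSE],
                    group = grp)
  })
  names(out) <- groups
  structure(out, class = "reference_panel_set")
}
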
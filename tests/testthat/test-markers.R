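# in-silico genotyping operators: PCR, variant editing, digestion, calling

panel <- oak_marker_panel()
templates <- make_marker_templates(seed = 1)

test_that("in-silico PCR reproduces the published amplicon lengths", {
  cases <- list(
    list("QP_miSeq14a", "robur", 187L), list("QP_miSeq14a", "petraea", 187L),
    list("QP_miSeq32", "robur", 188L), list("QP_miSeq32", "petraea", 193L),
    list("QP_miSeq32", "caucasus-petraea", 188L),
    list("QP_miSeq36", "robur", 169L), list("QP_miSeq36", "petraea", 169L),
    list("QP_miSeq38", "robur", 193L), list("QP_miSeq38", "petraea", 193L)
  )
  for (cs in cases) {
    amp <- extract_amplicon(template_sequence(templates, cs[[1]], cs[[2]]),
                            panel[[cs[[1]]]])
    expect_equal(amp$length, cs[[3]],
                 info = paste(cs[[1]], cs[[2]]))
    expect_equal(nchar(amp$sequence), amp$length)
    # forward primer always at the 5' end of the product
    expect_equal(substr(amp$sequence, 1, nchar(panel[[cs[[1]]]]$fwd)),
                 panel[[cs[[1]]]]$fwd)
  }
})

test_that("templates stored on the minus strand are re-oriented", {
  amp <- extract_amplicon(template_sequence(templates, "QP_miSeq36", "robur"),
                          panel$QP_miSeq36)
  expect_equal(amp$strand, "-")
})

test_that("extraction fails informatively without a unique product", {
  expect_error(extract_amplicon(paste(rep("A", 300), collapse = ""),
                                panel$QP_miSeq32), "no in-silico PCR")
  dbl <- paste0(template_sequence(templates, "QP_miSeq32", "robur"),
                template_sequence(templates, "QP_miSeq32", "robur"))
  expect_error(extract_amplicon(dbl, panel$QP_miSeq32), "candidate")
})

test_that("restriction digestion reproduces the published fragments", {
  amp <- function(m, a) {
    extract_amplicon(template_sequence(templates, m, a), panel[[m]])$sequence
  }
  expect_equal(digest(amp("QP_miSeq14a", "petraea"), panel$QP_miSeq14a$enzyme),
               c(80L, 107L))
  expect_equal(digest(amp("QP_miSeq14a", "robur"), panel$QP_miSeq14a$enzyme),
               187L)
  expect_equal(digest(amp("QP_miSeq36", "robur"), panel$QP_miSeq36$enzyme),
               c(86L, 83L))
  expect_equal(digest(amp("QP_miSeq36", "petraea"), panel$QP_miSeq36$enzyme),
               169L)
})

test_that("digestion matches a scan-and-split oracle and conserves length", {
  withr::local_seed(7)
  for (enz in list(restriction_enzyme("MboI"), restriction_enzyme("MseI"))) {
    for (rep in 1:25) {
      s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
      got <- digest(s, enz)
      expect_equal(got, oracle_digest(s, enz$site, enz$cut_offset))
      expect_equal(sum(got), nchar(s))
    }
  }
  expect_error(digest("", restriction_enzyme("MboI")), "empty")
})

test_that("variant editing handles substitutions, insertions, deletions", {
  expect_equal(apply_variant("AATTAA", 3, "T", "G"), "AAGTAA")
  expect_equal(apply_variant("AATTAA", 3, "-", "CCC"), "AACCCTTAA")
  expect_equal(apply_variant("AACCCTTAA", 3, "CCC", "-"), "AATTAA")
  expect_equal(apply_variant("AATTAA", 3, "T", "T"), "AATTAA")
  expect_error(apply_variant("AATTAA", 3, "G", "C"), "mismatch")

  # length change always equals the allele length difference
  withr::local_seed(11)
  for (rep in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    off <- sample(50, 1)
    if (runif(1) < 0.5) {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1), TRUE),
                   collapse = "")
      out <- apply_variant(s, off, "-", ins)
      expect_equal(nchar(out), nchar(s) + nchar(ins))
    } else {
      ref <- substr(s, off, off)
      alt <- sample(c("A", "C", "G", "T"), 1)
      out <- apply_variant(s, off, ref, alt)
      expect_equal(nchar(out), nchar(s))
      expect_equal(substr(out, off, off), alt)
    }
  }
})

test_that("the InDel insertion turns the 188 bp product into 193 bp", {
  m <- panel$QP_miSeq32
  amp <- extract_amplicon(template_sequence(templates, "QP_miSeq32", "robur"),
                          m)
  edited <- apply_variant(amp$sequence, m$loci$amplicon_offset, "-", "GCTTC")
  expect_equal(nchar(edited), 193L)
  # editing the template and re-amplifying gives the same product
  tpl_edit <- apply_variant(
    template_sequence(templates, "QP_miSeq32", "robur"),
    templates$records[["QP_miSeq32|robur"]]$amplicon_span[1] +
      m$loci$amplicon_offset - 1L, "-", "GCTTC")
  expect_equal(extract_amplicon(tpl_edit, m)$sequence, edited)
})

test_that("amplicon extraction commutes with interior edits", {
  m <- panel$QP_miSeq38
  tpl <- template_sequence(templates, "QP_miSeq38", "robur")
  span <- templates$records[["QP_miSeq38|robur"]]$amplicon_span
  for (off in c(90L, 120L)) {
    ref <- substr(tpl, span[1] + off - 1L, span[1] + off - 1L)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    route1 <- extract_amplicon(apply_variant(tpl, span[1] + off - 1L,
                                             ref, alt), m)$sequence
    route2 <- apply_variant(extract_amplicon(tpl, m)$sequence, off, ref, alt)
    expect_equal(route1, route2)
  }
})

test_that("genotype calls map observations onto allele pairs", {
  m14 <- panel$QP_miSeq14a
  expect_equal(call_locus(m14, c(187, 80, 107))$genotype, c("C/T", "C/T"))
  expect_equal(call_locus(m14, c(80, 107))$genotype, c("C/C", "T/T"))
  expect_equal(call_locus(m14, 187)$genotype, c("T/T", "C/C"))

  m32 <- panel$QP_miSeq32
  expect_equal(call_locus(m32, c(188, 193))$genotype, "188/193")
  expect_equal(call_locus(m32, c(188, 188))$genotype, "188/188")
  expect_equal(call_locus(m32, 193)$genotype, "193/193")

  m36 <- panel$QP_miSeq36
  expect_equal(call_locus(m36, 169)$genotype, "C/C")
  expect_equal(call_locus(m36, c(86, 83, 169))$genotype, "C/T")

  m38 <- panel$QP_miSeq38
  got <- call_locus(m38, list(QP_miSeq38_SNP1 = "R", QP_miSeq38_SNP2 = "A"))
  expect_equal(got$genotype, c("A/G", "A/A"))
  # CAPS markers can also be read from Sanger traces of the amplicon
  expect_equal(call_locus(m14, list(QP_miSeq14a_SNP1 = "Y",
                                    QP_miSeq14a_SNP2 = "C"),
                          mode = "sanger")$genotype,
               c("C/T", "C/C"))
  expect_error(call_locus(panel$QP_miSeq32, 188, mode = "sanger"),
               "genotyped by")
})

test_that("unmatchable observations give missing calls with a warning", {
  expect_warning(g <- call_locus(panel$QP_miSeq14a, c(50, 60)), "no defined")
  expect_true(all(is.na(g$genotype)))
  expect_warning(g2 <- call_locus(panel$QP_miSeq32, 150), "no defined")
  expect_true(is.na(g2$genotype))
  expect_warning(g3 <- call_locus(panel$QP_miSeq36, list(QP_miSeq36 = "G"),
                                  mode = "sanger"), "no defined")
  expect_true(is.na(g3$genotype))
  expect_warning(g4 <- call_locus(panel$QP_miSeq36, "not-a-length"),
                 "non-numeric")
  expect_true(is.na(g4$genotype))
})

test_that("in-silico diploid genotyping is exact on synthetic material", {
  hap <- function(m, a) template_sequence(templates, m, a)
  for (mid in names(panel)) {
    m <- panel[[mid]]
    hom_r <- call_locus(m, c(hap(mid, "robur"), hap(mid, "robur")),
                        mode = "insilico")
    hom_p <- call_locus(m, c(hap(mid, "petraea"), hap(mid, "petraea")),
                        mode = "insilico")
    het <- call_locus(m, c(hap(mid, "robur"), hap(mid, "petraea")),
                      mode = "insilico")
    for (i in seq_len(nrow(m$loci))) {
      rob <- m$loci$allele_rob[i]
      pet <- m$loci$allele_pet[i]
      expect_equal(hom_r$genotype[i], paste(rob, rob, sep = "/"))
      expect_equal(hom_p$genotype[i], paste(pet, pet, sep = "/"))
      expect_equal(het$genotype[i],
                   paste(sort(c(rob, pet), method = "radix"),
                         collapse = "/"))
      # homozygous material never reads as a heterozygote
      expect_false(grepl("/", hom_r$genotype[i]) &&
                     length(unique(strsplit(hom_r$genotype[i],
                                            "/")[[1]])) > 1)
    }
  }
})

test_that("the shipped panel definition file round-trips", {
  path <- system.file("extdata", "oak_marker_panel.txt", package = "oakdiff")
  skip_if(path == "", "installed extdata not found")
  expect_equal(read_marker_panel(path), panel)
  tmp <- tempfile(fileext = ".txt")
  write_marker_panel(panel, tmp)
  expect_equal(read_marker_panel(tmp), panel)
})
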
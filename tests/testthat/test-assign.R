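# Bayesian multilocus assignment: predictive probabilities, scores,
# exclusion probabilities, self-assignment, summaries and notes

test_that("predictive genotype probabilities match the closed forms", {
  # k = 2, counts {A:10, B:0}, prior 1/k = 0.5
  expect_equal(predictive_genotype_prob(c("A", "A"), c(A = 10), k = 2),
               10.5 * 11.5 / (11 * 12))
  expect_equal(predictive_genotype_prob(c("A", "B"), c(A = 10), k = 2),
               2 * 10.5 * 0.5 / (11 * 12))
  expect_equal(round(predictive_genotype_prob(c("A", "A"), c(A = 10), 2), 6),
               0.914773)
  expect_equal(round(predictive_genotype_prob(c("A", "B"), c(A = 10), 2), 6),
               0.079545)
  # "A/B" string form is accepted
  expect_equal(predictive_genotype_prob("A/B", c(A = 10), k = 2),
               predictive_genotype_prob(c("A", "B"), c(A = 10), k = 2))
})

test_that("per-locus predictive probabilities sum to one", {
  withr::local_seed(5)
  for (k in 1:5) {
    alleles <- LETTERS[seq_len(k)]
    for (rep in 1:6) {
      counts <- stats::setNames(sample(0:30, k, replace = TRUE), alleles)
      for (tau in c(1 / k, 1)) {
        total <- 0
        for (i in seq_len(k)) {
          for (j in i:k) {
            total <- total +
              predictive_genotype_prob(c(alleles[i], alleles[j]), counts,
                                       k, tau)
          }
        }
        expect_equal(total, 1)
      }
    }
  }
})

test_that("predictive probabilities match the Dirichlet-integral oracle", {
  cases <- list(
    list(g = c("A", "A"), counts = c(A = 10, B = 0), k = 2),
    list(g = c("A", "B"), counts = c(A = 7, B = 3), k = 2),
    list(g = c("B", "B"), counts = c(A = 2, B = 13), k = 2),
    list(g = c("A", "C"), counts = c(A = 5, B = 2, C = 1), k = 3),
    list(g = c("C", "C"), counts = c(A = 4, B = 4, C = 0), k = 3)
  )
  for (cs in cases) {
    expect_equal(predictive_genotype_prob(cs$g, cs$counts, cs$k),
                 oracle_predictive(cs$g, cs$counts, cs$k),
                 tolerance = 1e-6)
  }
})

test_that("multilocus likelihood is the product of per-locus predictives", {
  a <- tiny_panel("A", L1 = c("A/A", "A/A", "A/B"),
                  L2 = c("C/C", "C/D", "C/C"),
                  L3 = c("E/E", "E/F", "E/E"),
                  L4 = c("G/G", "G/H", "H/H"))
  q <- query_row("q", L1 = "A/A", L2 = "C/D", L3 = "E/E", L4 = "G/H")
  cfg <- assignment_config(min_typed = 4)
  got <- multilocus_log_likelihood(q, a, list(a), cfg)
  want <- log(oracle_predictive(c("A", "A"), c(A = 5, B = 1), 2)) +
    log(oracle_predictive(c("C", "D"), c(C = 5, D = 1), 2)) +
    log(oracle_predictive(c("E", "E"), c(E = 5, F = 1), 2)) +
    log(oracle_predictive(c("G", "H"), c(G = 3, H = 3), 2))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("adding an observed allele increases its homozygote probability", {
  for (n_a in 0:20) {
    p1 <- predictive_genotype_prob(c("A", "A"), c(A = n_a, B = 5), 2)
    p2 <- predictive_genotype_prob(c("A", "A"), c(A = n_a + 1, B = 5), 2)
    expect_gt(p2, p1)
  }
})

test_that("samples typed below the locus minimum are rejected", {
  panels <- make_reference_panels(panel_config(seed = 1))
  q <- modal_petraea_query("undertyped")
  q$QP_miSeq32 <- NA
  q$QP_miSeq36 <- NA
  q$QP_miSeq38_SNP1 <- NA
  expect_error(assignment_scores(q, panels), "at least 4")
  expect_error(multilocus_log_likelihood(q, panels$QUPET, panels),
               "undertyped")
})

test_that("assignment scores normalize, permute and detect symmetry", {
  a <- tiny_panel("A", L1 = rep("A/A", 5), L2 = rep("C/C", 5),
                  L3 = rep("E/E", 5), L4 = rep("G/G", 5))
  q <- query_row("q", L1 = "A/A", L2 = "C/C", L3 = "E/E", L4 = "G/G")
  cfg <- assignment_config(min_typed = 4)
  same <- assignment_scores(q, list(X = a, Y = a, Z = a), cfg)
  expect_equal(unname(same$scores), rep(1 / 3, 3))
  expect_true(same$tie)

  # two opposed single-locus panels reproduce the frozen score ratio
  pa <- tiny_panel("PA", L1 = rep("A/A", 5))
  pb <- tiny_panel("PB", L1 = rep("B/B", 5))
  q1 <- query_row("q", L1 = "A/A")
  cfg1 <- assignment_config(min_typed = 1)
  sc <- assignment_scores(q1, list(PA = pa, PB = pb), cfg1)
  expect_equal(sum(sc$scores), 1)
  expect_equal(round(unname(sc$scores), 5), c(0.99383, 0.00617))
  # permuting the panel order permutes the scores identically
  sc_rev <- assignment_scores(q1, list(PB = pb, PA = pa), cfg1)
  expect_equal(sc_rev$scores[["PA"]], sc$scores[["PA"]])
  expect_equal(sc_rev$assigned, "PA")
})

test_that("a fully petraea-modal genotype scores 1.000 at three decimals", {
  panels <- make_reference_panels(panel_config(seed = 1))
  sc <- assignment_scores(modal_petraea_query(), panels)
  expect_equal(round(sc$scores[["QUPET"]], 3), 1)
  expect_equal(round(sc$scores[["QUROB"]], 3), 0)
  expect_equal(sc$assigned, "QUPET")
  sc_r <- assignment_scores(modal_robur_query(), panels)
  expect_equal(sc_r$assigned, "QUROB")
})

test_that("exclusion probability is 0 for the modal monomorphic genotype", {
  mono <- tiny_panel("M", L1 = rep("A/A", 8))
  q <- query_row("q", L1 = "A/A")
  cfg <- assignment_config(min_typed = 1, n_sim = 500, seed = 3)
  expect_equal(exclusion_probability(q, mono, list(mono), cfg), 0)
})

test_that("alien six-locus genotypes are excluded almost surely", {
  panels <- make_reference_panels(panel_config(seed = 1))
  alien <- query_row("alien", "unknown",
                     QP_miSeq14a_SNP1 = "G/G", QP_miSeq14a_SNP2 = "G/G",
                     QP_miSeq32 = "240/240", QP_miSeq36 = "G/G",
                     QP_miSeq38_SNP1 = "T/T", QP_miSeq38_SNP2 = "T/T")
  cfg <- assignment_config(n_sim = 2000, seed = 4)
  for (grp in names(panels)) {
    expect_gte(exclusion_probability(alien, panels[[grp]], panels, cfg),
               0.99)
  }
})

test_that("exclusion probabilities of panel-drawn queries are near-uniform", {
  # balanced three-allele loci keep likelihood ties rare, so the
  # probability-integral-transform argument applies
  withr::local_seed(42)
  loci <- paste0("L", 1:8)
  freqs <- lapply(1:8, function(i) {
    p <- c(0.5, 0.3, 0.2)[sample(1:3)]
    names(p) <- c("A", "B", "C")
    p
  })
  draw_ind <- function(id) {
    g <- vapply(seq_along(loci), function(j) {
      a <- sample(names(freqs[[j]]), 2, TRUE, prob = freqs[[j]])
      paste(sort(a), collapse = "/")
    }, character(1))
    out <- data.frame(sample_id = id, group = "SIM", t(g),
                      stringsAsFactors = FALSE)
    names(out) <- c("sample_id", "group", loci)
    out
  }
  panel <- reference_panel(
    do.call(rbind, lapply(1:30, function(i) draw_ind(paste0("P", i)))),
    group = "SIM")
  cfg <- assignment_config(n_sim = 1000, min_typed = 4)
  excl <- vapply(1:500, function(i) {
    q <- simulate_individual(panel, sample_id = "q")
    exclusion_probability(q, panel, list(panel), cfg)
  }, numeric(1))
  expect_gt(mean(excl), 0.45)
  expect_lt(mean(excl), 0.55)
  ks <- suppressWarnings(stats::ks.test(excl, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("identical seeds give identical exclusion probabilities", {
  panels <- make_reference_panels(panel_config(seed = 1))
  q <- modal_petraea_query()
  cfg <- assignment_config(n_sim = 400, seed = 11)
  e1 <- exclusion_probability(q, panels$QUPET, panels, cfg)
  e2 <- exclusion_probability(q, panels$QUPET, panels, cfg)
  expect_identical(e1, e2)
})

test_that("posterior-mean frequencies recover the generating frequencies", {
  withr::local_seed(17)
  p_true <- c(A = 0.7, B = 0.3)
  n <- 150
  g <- replicate(n, paste(sort(sample(names(p_true), 2, TRUE,
                                      prob = p_true)), collapse = "/"))
  panel <- tiny_panel("SIM", L1 = g)
  counts <- allele_counts(panel, "L1")
  post <- (counts + 0.5) / (sum(counts) + 1)
  se <- sqrt(p_true[["A"]] * (1 - p_true[["A"]]) / (2 * n))
  expect_lt(abs(post[["A"]] - p_true[["A"]]), 3 * se)
})

test_that("leave-one-out self-assignment keeps pure panels mostly home", {
  # larger panels simulated from the published allele frequencies
  base <- make_reference_panels(panel_config(seed = 2))
  withr::local_seed(23)
  big <- function(src, n) {
    rows <- do.call(rbind, lapply(seq_len(n), function(i) {
      simulate_individual(src, sample_id = sprintf("%s_%03d", src$group, i))
    }))
    reference_panel(rows, group = src$group)
  }
  panels <- list(QUROB = big(base$QUROB, 200), QUPET = big(base$QUPET, 200),
                 Hybrid = base$Hybrid)
  sa <- self_assignment(panels, assignment_config(n_sim = 10),
                        leave_one_out = TRUE, compute_exclusion = FALSE)
  pure <- sa[sa$group %in% c("QUROB", "QUPET"), ]
  expect_lt(mean(pure$assigned != pure$group), 0.05)
})

test_that("self-assignment requires at least two members for leave-one-out", {
  a <- tiny_panel("A", L1 = "A/A")
  b <- tiny_panel("B", L1 = c("B/B", "B/B"))
  expect_error(self_assignment(list(A = a, B = b),
                               assignment_config(min_typed = 1),
                               compute_exclusion = FALSE),
               "fewer than 2")
})

test_that("clone panels self-assign home with score near one", {
  a <- tiny_panel("A", L1 = rep("A/A", 6), L2 = rep("C/C", 6),
                  L3 = rep("E/E", 6), L4 = rep("G/G", 6))
  b <- tiny_panel("B", L1 = rep("B/B", 6), L2 = rep("D/D", 6),
                  L3 = rep("F/F", 6), L4 = rep("H/H", 6))
  sa <- self_assignment(list(A = a, B = b),
                        assignment_config(min_typed = 4),
                        compute_exclusion = FALSE,
                        species_groups = c("A", "B"))
  expect_true(all(sa$assigned == sa$group))
  expect_true(all(sa$score_A[sa$group == "A"] > 0.99))
})

test_that("panel summaries reproduce reconstructed class percentages", {
  panels <- make_reference_panels(panel_config(seed = 1))
  s <- summarize_panel(panels$QUPET)
  snp1 <- s[s$locus == "QP_miSeq14a_SNP1", ]
  expect_equal(snp1$pct[snp1$genotype == "C/C"], 84L)
  expect_equal(snp1$pct[snp1$genotype == "C/T"], 16L)
  expect_true(all(tapply(s$pct, s$locus, sum) == 100))
  one <- tiny_panel("ONE", L1 = "A/B")
  s1 <- summarize_panel(one)
  expect_equal(s1$pct, 100L)
  empty <- reference_panel(data.frame(sample_id = character(0),
                                      group = character(0),
                                      L1 = character(0),
                                      stringsAsFactors = FALSE),
                           group = "E")
  expect_error(summarize_panel(empty), "empty")
})

test_that("divergent-marker notes follow the reporting conventions", {
  panels <- make_reference_panels(panel_config(seed = 1))
  q <- modal_petraea_query()
  q$group <- "QUPET"
  expect_length(divergent_marker_report(q, panels, "QUPET"), 0)

  q36 <- q
  q36$QP_miSeq36 <- "C/T"
  expect_equal(divergent_marker_report(q36, panels, "QUPET"), "36 hetero")

  qhomo <- q
  qhomo$QP_miSeq36 <- "T/T"
  expect_equal(divergent_marker_report(qhomo, panels, "QUPET"),
               "36 homo QR")

  qmiss <- modal_robur_query()
  qmiss$QP_miSeq14a_SNP1 <- NA
  qmiss$QP_miSeq14a_SNP2 <- NA
  expect_equal(divergent_marker_report(qmiss, panels, "QUROB"),
               "14 missing")

  # both SNPs of a region heterozygous collapse to one note
  q38 <- modal_robur_query()
  q38$QP_miSeq38_SNP1 <- "A/G"
  q38$QP_miSeq38_SNP2 <- "A/C"
  expect_equal(divergent_marker_report(q38, panels, "QUROB"), "38 hetero")
})

test_that("assignment tables round-trip through TSV and keep rounding", {
  panels <- make_reference_panels(panel_config(seed = 1))
  q <- rbind(modal_petraea_query("q1"), modal_robur_query("q2"))
  res <- assign_samples(q, panels, assignment_config(n_sim = 200, seed = 5))
  expect_equal(res$assigned, c("QUPET", "QUROB"))
  expect_equal(rowSums(res[, paste0("score_", names(panels))]),
               c(1, 1), ignore_attr = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_assignment_table(res, path, "tsv")
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$score_QUPET, round(res$score_QUPET, 3))
  jpath <- tempfile(fileext = ".json")
  write_assignment_table(res, jpath, "json")
  full <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(full$score_QUPET, res$score_QUPET, tolerance = 1e-12)
})
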
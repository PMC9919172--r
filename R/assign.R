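# Bayesian multilocus assignment to reference groups.
#
# The genotype likelihood under a reference group integrates the unknown
# population allele frequencies over their Dirichlet posterior given the
# panel's allele counts (Rannala-Mountain predictive probabilities). With
# per-allele prior parameter tau and S = k * tau:
#   P(a/b | panel) = 2 (n_a + tau)(n_b + tau) / ((n + S)(n + S + 1))
#   P(a/a | panel) =   (n_a + tau)(n_a + tau + 1) / ((n + S)(n + S + 1))
# The default prior is tau = 1/k (k = number of distinct alleles at the
# locus across all reference groups plus the query), so S = 1.

#' Assignment configuration
#'
#' @param prior_style `"rannala-mountain"` (Dirichlet parameter `1/k`
#'   per allele, the default) or `"uniform"` (Dirichlet(1)).
#' @param min_typed Minimum number of non-missing loci a sample needs to
#'   be assignable (default 4 of the 6 panel loci).
#' @param n_sim Monte-Carlo draws for exclusion probabilities.
#' @param seed RNG seed for the exclusion simulation (`NULL` = current
#'   stream).
#' @param exclusion_threshold Exclusion probabilities below this value
#'   mean a false-positive assignment to that group is improbable
#'   (default 0.95).
#' @param score_decimals Decimals used when formatting scores in reports.
#' @return An object of class `assignment_config`.
#' @export
assignment_config <- function(prior_style = c("rannala-mountain", "uniform"),
                              min_typed = 4L, n_sim = 10000L, seed = NULL,
                              exclusion_threshold = 0.95,
                              score_decimals = 3L) {
  prior_style <- match.arg(prior_style)
  stopifnot(n_sim >= 1L, exclusion_threshold > 0, exclusion_threshold < 1,
            min_typed >= 1L)
  structure(list(prior_style = prior_style, min_typed = min_typed,
                 n_sim = n_sim, seed = seed,
                 exclusion_threshold = exclusion_threshold,
                 score_decimals = score_decimals),
            class = "assignment_config")
}

prior_tau <- function(k, cfg) {
  switch(cfg$prior_style, "rannala-mountain" = 1 / k, uniform = 1)
}

#' Predictive probability of a genotype given panel allele counts
#'
#' The Dirichlet-multinomial (Rannala-Mountain) predictive probability of
#' drawing the unordered genotype from a population whose allele
#' frequencies have been integrated over their posterior given the
#' reference counts. Alleles unseen in the panel receive prior mass only.
#'
#' @param genotype Character vector of the two allele labels (or a
#'   single `"A/B"` string).
#' @param counts Named vector of panel allele counts at the locus.
#' @param k Number of distinct alleles at the locus across all reference
#'   groups and the query (allele universe size).
#' @param tau Per-allele Dirichlet prior parameter (default `1/k`).
#' @return The genotype probability.
#' @export
#' @examples
#' predictive_genotype_prob(c("A", "A"), c(A = 10), k = 2)  # 0.9147727
predictive_genotype_prob <- function(genotype, counts, k, tau = 1 / k) {
  if (length(genotype) == 1L) genotype <- geno_alleles(genotype)
  stopifnot(length(genotype) == 2L, k >= 1L, all(counts >= 0))
  n <- sum(counts)
  S <- k * tau
  cnt <- function(a) if (a %in% names(counts)) counts[[a]] else 0
  a <- genotype[1]
  b <- genotype[2]
  denom <- (n + S) * (n + S + 1)
  if (a == b) {
    (cnt(a) + tau) * (cnt(a) + tau + 1) / denom
  } else {
    2 * (cnt(a) + tau) * (cnt(b) + tau) / denom
  }
}

# allele universe per locus: distinct alleles across all panels + query
locus_universe <- function(panels, loci, query = NULL) {
  out <- lapply(loci, function(l) {
    alleles <- unlist(lapply(panels, function(p) names(allele_counts(p, l))))
    if (!is.null(query) && !is_missing_geno(query[[l]])) {
      alleles <- c(alleles, geno_alleles(query[[l]]))
    }
    sort(unique(alleles), method = "radix")
  })
  names(out) <- loci
  out
}

# per-locus counts of one panel, optionally leave-one-out
panel_counts <- function(panel, loci, exclude_sample = NULL) {
  out <- lapply(loci, allele_counts, panel = panel,
                exclude_sample = exclude_sample)
  names(out) <- loci
  out
}

typed_loci <- function(genotype_row, loci) {
  loci[!vapply(loci, function(l) is_missing_geno(genotype_row[[l]]),
               logical(1))]
}

#' Multilocus log-likelihood of a genotype under one reference panel
#'
#' Sum of log predictive genotype probabilities over the sample's
#' non-missing loci (loci treated as independent). Missing loci are
#' skipped; samples typed at fewer than `cfg$min_typed` loci are
#' rejected.
#'
#' @param genotype_row One-row genotype data.frame (or named list) with
#'   the locus columns.
#' @param panel A [reference_panel()].
#' @param panels All reference panels (used for the allele universe);
#'   defaults to `list(panel)`.
#' @param cfg An [assignment_config()].
#' @param loci Locus names; default: the panel's loci.
#' @return Log probability.
#' @export
multilocus_log_likelihood <- function(genotype_row, panel,
                                      panels = list(panel),
                                      cfg = assignment_config(),
                                      loci = panel$loci) {
  typed <- typed_loci(genotype_row, loci)
  if (length(typed) < cfg$min_typed) {
    stopf("sample %s: typed at %d loci, need at least %d",
          genotype_row[["sample_id"]] %||% "?", length(typed),
          cfg$min_typed)
  }
  universe <- locus_universe(panels, typed, query = genotype_row)
  counts <- panel_counts(panel, typed)
  sum(vapply(typed, function(l) {
    k <- length(universe[[l]])
    log(predictive_genotype_prob(genotype_row[[l]], counts[[l]], k,
                                 prior_tau(k, cfg)))
  }, numeric(1)))
}

# internal scoring core working on precomputed counts/universe
score_genotype <- function(genotype_row, counts_by_group, universe, cfg) {
  typed <- names(universe)
  ll <- vapply(counts_by_group, function(counts) {
    sum(vapply(typed, function(l) {
      k <- length(universe[[l]])
      log(predictive_genotype_prob(genotype_row[[l]], counts[[l]], k,
                                   prior_tau(k, cfg)))
    }, numeric(1)))
  }, numeric(1))
  m <- max(ll)
  if (!is.finite(m)) {
    stopf("sample %s: all group likelihoods underflow; inspect the prior",
          genotype_row[["sample_id"]] %||% "?")
  }
  w <- exp(ll - m)
  list(log_lik = ll, scores = w / sum(w))
}

#' Normalized assignment scores of one sample
#'
#' Computes the per-group likelihoods of the sample's multilocus genotype
#' and normalizes them to scores summing to 1 (in log space with
#' max-subtraction). The assigned group is the argmax; exact ties are
#' reported explicitly.
#'
#' @param genotype_row One-row genotype data.frame.
#' @param panels Named list of [reference_panel()] objects.
#' @param cfg An [assignment_config()].
#' @return List of class `assignment_scores`: `sample_id`, `scores`
#'   (named), `log_lik` (named), `assigned` (ties joined by `"|"`),
#'   `tie` flag and `n_typed`.
#' @export
assignment_scores <- function(genotype_row, panels,
                              cfg = assignment_config()) {
  typed <- typed_loci(genotype_row, panels[[1]]$loci)
  if (length(typed) < cfg$min_typed) {
    stopf("sample %s: typed at %d loci, need at least %d",
          genotype_row[["sample_id"]] %||% "?", length(typed),
          cfg$min_typed)
  }
  universe <- locus_universe(panels, typed, query = genotype_row)
  counts_by_group <- lapply(panels, panel_counts, loci = typed)
  sc <- score_genotype(genotype_row, counts_by_group, universe, cfg)
  top <- which(sc$log_lik >= max(sc$log_lik) - 1e-9)
  structure(
    list(sample_id = genotype_row[["sample_id"]] %||% NA_character_,
         scores = sc$scores, log_lik = sc$log_lik,
         assigned = paste(names(panels)[top], collapse = "|"),
         tie = length(top) > 1L, n_typed = length(typed)),
    class = "assignment_scores"
  )
}

#' @export
print.assignment_scores <- function(x, ...) {
  cat(sprintf("<assignment_scores> %s -> %s\n", x$sample_id, x$assigned))
  print(round(x$scores, 4))
  invisible(x)
}

# per-locus tables driving the exclusion simulation under one panel
exclusion_tables <- function(counts_by_locus, universe, cfg) {
  lapply(names(universe), function(l) {
    alleles <- universe[[l]]
    k <- length(alleles)
    tau <- prior_tau(k, cfg)
    counts <- counts_by_locus[[l]]
    n_a <- stats::setNames(rep(0, k), alleles)
    n_a[names(counts)] <- counts
    p <- (n_a + tau) / (sum(n_a) + k * tau)
    idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
    glog <- numeric(nrow(idx))
    gprob <- numeric(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      a <- alleles[idx[r, 1]]
      b <- alleles[idx[r, 2]]
      glog[r] <- log(predictive_genotype_prob(c(a, b), counts, k, tau))
      gprob[r] <- if (a == b) p[[a]]^2 else 2 * p[[a]] * p[[b]]
    }
    list(log_prob = glog, sim_prob = gprob)
  })
}

#' Monte-Carlo exclusion probability of a genotype under a panel
#'
#' Simulates `cfg$n_sim` multilocus genotypes from the panel by drawing,
#' at each locus typed in the query, two alleles independently from the
#' panel's posterior-mean allele frequencies `(n_a + tau) / (n + S)`,
#' and returns the proportion of simulants whose log-likelihood under
#' the panel strictly exceeds the query's. Values near 1 mean the query
#' is atypical for the panel; values below `cfg$exclusion_threshold`
#' (default 0.95) mean a false-positive assignment to this group is
#' improbable.
#'
#' @param genotype_row One-row genotype data.frame.
#' @param panel The reference panel tested for exclusion.
#' @param panels All panels (allele universe); defaults to
#'   `list(panel)`.
#' @param cfg An [assignment_config()] (its `seed`, if set, makes the
#'   simulation reproducible).
#' @return Exclusion probability in `[0, 1]`.
#' @export
exclusion_probability <- function(genotype_row, panel,
                                  panels = list(panel),
                                  cfg = assignment_config()) {
  with_seed_if(cfg$seed)
  typed <- typed_loci(genotype_row, panel$loci)
  if (length(typed) < cfg$min_typed) {
    stopf("sample %s: typed at %d loci, need at least %d",
          genotype_row[["sample_id"]] %||% "?", length(typed),
          cfg$min_typed)
  }
  universe <- locus_universe(panels, typed, query = genotype_row)
  counts <- panel_counts(panel, typed)
  ll_obs <- sum(vapply(typed, function(l) {
    k <- length(universe[[l]])
    log(predictive_genotype_prob(genotype_row[[l]], counts[[l]], k,
                                 prior_tau(k, cfg)))
  }, numeric(1)))
  exclusion_mc(counts, universe, cfg, ll_obs)
}

exclusion_mc <- function(counts_by_locus, universe, cfg, ll_obs) {
  tabs <- exclusion_tables(counts_by_locus, universe, cfg)
  ll_sim <- numeric(cfg$n_sim)
  for (tb in tabs) {
    ll_sim <- ll_sim +
      sample(tb$log_prob, cfg$n_sim, replace = TRUE, prob = tb$sim_prob)
  }
  mean(ll_sim > ll_obs + 1e-9)
}

#' Assign query samples to reference groups
#'
#' Scores every query sample against the reference panels, computes
#' Monte-Carlo exclusion probabilities per group and a divergent-marker
#' note, and returns one table row per sample (the layout of the
#' published assignment tables).
#'
#' @param query Genotype data.frame of the samples to assign.
#' @param panels Named list of [reference_panel()] objects.
#' @param cfg An [assignment_config()].
#' @param compute_exclusion Compute exclusion probabilities (set `FALSE`
#'   to skip the Monte-Carlo step).
#' @param species_groups The two pure-species group labels used for
#'   divergent-marker notes.
#' @return data.frame of class `assignment_table`: `sample_id`,
#'   `group`, one `score_*` and (optionally) one `excl_*` column per
#'   group, `assigned`, `tie`, `n_typed`, `divergent`.
#' @export
assign_samples <- function(query, panels, cfg = assignment_config(),
                           compute_exclusion = TRUE,
                           species_groups = intersect(c("QUROB", "QUPET"),
                                                      names(panels))) {
  with_seed_if(cfg$seed)
  inner <- cfg
  inner$seed <- NULL                 # one seeding for the whole batch
  rows <- lapply(seq_len(nrow(query)), function(i) {
    g <- query[i, , drop = FALSE]
    sc <- assignment_scores(g, panels, inner)
    excl <- if (compute_exclusion) {
      vapply(names(panels), function(grp) {
        exclusion_probability(g, panels[[grp]], panels, inner)
      }, numeric(1))
    } else {
      stats::setNames(rep(NA_real_, length(panels)), names(panels))
    }
    nominal <- g$group %||% NA_character_
    ref_group <- if (!is.na(nominal) && nominal %in% species_groups) {
      nominal
    } else if (sub("\\|.*", "", sc$assigned) %in% species_groups) {
      sub("\\|.*", "", sc$assigned)
    } else {
      NA_character_
    }
    notes <- if (!is.na(ref_group)) {
      divergent_marker_report(g, panels, ref_group,
                              species_groups = species_groups)
    } else {
      character(0)
    }
    out <- data.frame(sample_id = g$sample_id, group = nominal,
                      stringsAsFactors = FALSE)
    for (grp in names(panels)) out[[paste0("score_", grp)]] <- sc$scores[[grp]]
    for (grp in names(panels)) out[[paste0("excl_", grp)]] <- excl[[grp]]
    out$assigned <- sc$assigned
    out$tie <- sc$tie
    out$n_typed <- sc$n_typed
    out$divergent <- if (length(notes)) paste(notes, collapse = "; ") else
      if (!is.na(ref_group)) paste("all", ref_group) else ""
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assignment_table", class(out))
  out
}

#' Leave-one-out self-assignment of the reference panels
#'
#' Scores every sufficiently typed member of every panel against the
#' three groups, removing the member from its own panel first (when
#' `leave_one_out`). Appends summary counts of correct and incorrect
#' assignments as an attribute.
#'
#' @param panels Named list of [reference_panel()] objects.
#' @param cfg An [assignment_config()].
#' @param leave_one_out Remove each member from its own panel before
#'   scoring (requires every panel to have at least 2 members).
#' @param compute_exclusion Compute exclusion probabilities.
#' @param species_groups Pure-species group labels for divergent notes.
#' @return An `assignment_table` (one row per scored member) with a
#'   `summary` attribute: per-group counts of members assigned home /
#'   elsewhere.
#' @export
self_assignment <- function(panels, cfg = assignment_config(),
                            leave_one_out = TRUE,
                            compute_exclusion = TRUE,
                            species_groups = intersect(c("QUROB", "QUPET"),
                                                       names(panels))) {
  with_seed_if(cfg$seed)
  inner <- cfg
  inner$seed <- NULL
  rows <- list()
  for (grp in names(panels)) {
    home <- panels[[grp]]
    if (leave_one_out && nrow(home$genotypes) < 2L) {
      stopf("panel %s has fewer than 2 members; cannot leave one out", grp)
    }
    for (i in seq_len(nrow(home$genotypes))) {
      g <- home$genotypes[i, , drop = FALSE]
      typed <- typed_loci(g, home$loci)
      if (length(typed) < cfg$min_typed) next
      universe <- locus_universe(panels, typed, query = g)
      counts_by_group <- lapply(names(panels), function(other) {
        panel_counts(panels[[other]], typed,
                     exclude_sample = if (leave_one_out && other == grp)
                       g$sample_id else NULL)
      })
      names(counts_by_group) <- names(panels)
      sc <- score_genotype(g, counts_by_group, universe, inner)
      top <- which(sc$log_lik >= max(sc$log_lik) - 1e-9)
      excl <- if (compute_exclusion) {
        vapply(names(panels), function(other) {
          ll_obs <- sc$log_lik[[other]]
          exclusion_mc(counts_by_group[[other]], universe, inner, ll_obs)
        }, numeric(1))
      } else {
        stats::setNames(rep(NA_real_, length(panels)), names(panels))
      }
      notes <- if (grp %in% species_groups) {
        divergent_marker_report(g, panels, grp,
                                species_groups = species_groups)
      } else {
        character(0)
      }
      row <- data.frame(sample_id = g$sample_id, group = grp,
                        stringsAsFactors = FALSE)
      for (g2 in names(panels)) row[[paste0("score_", g2)]] <- sc$scores[[g2]]
      for (g2 in names(panels)) row[[paste0("excl_", g2)]] <- excl[[g2]]
      row$assigned <- paste(names(panels)[top], collapse = "|")
      row$tie <- length(top) > 1L
      row$n_typed <- length(typed)
      row$divergent <- if (length(notes)) paste(notes, collapse = "; ") else
        if (grp %in% species_groups) paste("all", grp) else ""
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  smry <- do.call(rbind, lapply(split(out, out$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               assigned_home = sum(d$assigned == d$group),
               assigned_elsewhere = sum(d$assigned != d$group),
               stringsAsFactors = FALSE)
  }))
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  class(out) <- c("assignment_table", class(out))
  out
}

#' Divergent-marker notes for one sample
#'
#' Reports, per typed locus and relative to the sample's nominal species
#' group, `"<n> hetero"` for heterozygous loci, `"<n> homo QP"` /
#' `"<n> homo QR"` for loci homozygous for the other species' modal
#' allele, and `"<n> missing"` for untyped loci (`<n>` is the marker
#' region number). Fully modal samples give an empty note list.
#'
#' @param genotype_row One-row genotype data.frame.
#' @param panels Named list of reference panels.
#' @param nominal_group The sample's nominal species group.
#' @param species_groups The two pure-species group labels.
#' @return Character vector of notes (deduplicated, panel order).
#' @export
divergent_marker_report <- function(genotype_row, panels, nominal_group,
                                    species_groups = c("QUROB", "QUPET")) {
  stopifnot(nominal_group %in% species_groups)
  other <- setdiff(species_groups, nominal_group)[1]
  abbr <- c(QUROB = "QR", QUPET = "QP")
  loci <- panels[[nominal_group]]$loci
  modal <- function(grp, l) {
    counts <- allele_counts(panels[[grp]], l)
    names(counts)[which.max(counts)]
  }
  notes <- character(0)
  for (l in loci) {
    num <- regmatches(l, regexpr("[0-9]+", l))
    g <- genotype_row[[l]]
    if (is_missing_geno(g)) {
      notes <- c(notes, sprintf("%s missing", num))
      next
    }
    a <- geno_alleles(g)
    if (a[1] != a[2]) {
      notes <- c(notes, sprintf("%s hetero", num))
    } else if (a[1] == modal(other, l) && a[1] != modal(nominal_group, l)) {
      notes <- c(notes, sprintf("%s homo %s", num,
                                abbr[[other]] %||% other))
    }
  }
  unique(notes)
}

#' Write an assignment table
#'
#' TSV mirrors the published table layout (scores and exclusion
#' probabilities rounded to `cfg$score_decimals`); JSON keeps full
#' precision.
#'
#' @param x An `assignment_table`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param cfg An [assignment_config()] (for the report rounding).
#' @param header Optional provenance lines (TSV only).
#' @return `path`, invisibly.
#' @export
write_assignment_table <- function(x, path, format = c("tsv", "json"),
                                   cfg = assignment_config(),
                                   header = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.data.frame(unclass(x)), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
    return(invisible(path))
  }
  out <- as.data.frame(x)
  num <- grepl("^(score|excl)_", names(out))
  out[num] <- lapply(out[num], round, digits = cfg$score_decimals)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
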
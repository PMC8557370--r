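# Self-contained replication experiments on synthetic data. These bundle
# the full pipeline (generate -> featurize -> cross-validate -> interpret
# / footprint / scan) at fixed study conditions, so the package's
# headline behaviors can be recomputed from a single seed.

#' Planted-motif recovery experiment
#'
#' Generates a two-tissue enhancer world with one mutated motif copy per
#' active tissue, builds the one-vs-rest dataset for the first tissue
#' with occurrence features over the k = 4..6 code-word space, runs
#' 10-fold cross-validation at a fixed feature count, merges the fold
#' models, and reports whether the planted code word ranks among the top
#' merged positive coefficients.
#'
#' Study conditions (defaults): 1000 elements per tissue (about 1800
#' after removing shared elements), 300 bp elements, planted 6-mers
#' gataag / taaaca, per-position mutation probability 0.1, sharing
#' probability 0.1, q = 100.
#'
#' @param seed Integer seed driving data generation, folds and solvers.
#' @param n_per_tissue Elements per tissue.
#' @param element_length Element width in bp.
#' @param mutation Per-position motif mutation probability.
#' @param q Leapfrog feature-count target.
#' @param folds Cross-validation folds.
#' @param shuffle Permute labels before fitting (null control).
#' @param top Rank cutoff for the recovery check.
#' @param opts Solver options sized for this problem (see
#'   [klr_opts()]).
#' @return List with `cv` (a `klr_cv`), `top_words`, `planted_label`,
#'   `rank` (NA if absent), `recovered` (rank <= `top`), `pr_auc`,
#'   `baseline`, `n`.
#' @export
recovery_experiment <- function(seed, n_per_tissue = 1000L,
                                element_length = 300L, mutation = 0.1,
                                q = 100L, folds = 10L, shuffle = FALSE,
                                top = 10L,
                                opts = klr_opts(max_epochs = 8,
                                                tol = 1e-6,
                                                path_epochs = 2,
                                                max_bisect = 4,
                                                obj_every = 2,
                                                warn_nonconverged = FALSE)) {
  cfg <- synthetic_config(
    c("liver", "lung"), n_per_tissue, element_length = element_length,
    motif_per_tissue = c(liver = "gataag", lung = "taaaca"),
    motif_mutation_prob = mutation, sharing_prob = 0.1,
    seed = seed)
  sim <- generate_elements(cfg)
  space <- codeword_space(4L, 6L)
  spec <- leaves_collection(sim$elements, "liver")
  ds <- build_dataset(spec, sim$genome, space, mode = "occurrence")
  if (shuffle) ds$y <- with_seed(seed + 7L, sample(ds$y))
  cv <- suppressWarnings(
    cross_validate(ds, q_grid = as.integer(q), folds = folds,
                   seed = seed, opts = opts))
  merged <- merge_cv_models(lapply(cv$folds, function(f) f$model))
  tw <- top_code_words(merged, count = max(top, 10L))
  planted <- canonical_label("gataag")
  rank <- match(planted, tw$code_word)
  list(cv = cv, top_words = tw, planted_label = planted,
       rank = rank, recovered = !is.na(rank) && rank <= top,
       pr_auc = cv$pr_auc, baseline = cv$baseline, n = length(ds$y))
}

#' Footprint shift round-trip and protection experiment
#'
#' Generates unmutated planted elements with ATAC-like reads whose cut
#' sites are depleted over the planted motif, verifies that the Tn5
#' shift recovers every sampled cut site exactly, and contrasts the
#' code-word-aligned footprint profile with the element-center control.
#'
#' @param seed Integer seed.
#' @param n_per_tissue Elements per tissue.
#' @param depletion Cut-site density factor inside the protected window.
#' @param reads Reads per element.
#' @param W Profile half-width in bp.
#' @return List with `roundtrip_mismatches`, `center_flank_ratio`
#'   (code-word mode), `control_center_dev` and `control_band` (the
#'   element-center control's deviation at offset 0 versus its 2-sd
#'   band over the flanks), `profile`, `control`, `n_anchors`.
#' @export
footprint_experiment <- function(seed, n_per_tissue = 150L,
                                 depletion = 0.2, reads = 400L,
                                 W = 100L) {
  cfg <- synthetic_config(
    c("liver", "lung"), n_per_tissue, element_length = 300L,
    motif_per_tissue = c(liver = "gataag", lung = "taaaca"),
    motif_mutation_prob = 0, sharing_prob = 0,
    reads_per_element = reads, footprint_halfwidth = 15L,
    footprint_depletion = depletion, seed = seed)
  sim <- generate_elements(cfg)
  rd <- generate_atac_reads(cfg, sim$elements, sim$planted)
  fw <- rd$reads$strand == "+"
  shifted <- ifelse(fw, rd$reads$start + 4L, (rd$reads$end - 1L) - 5L)
  mism <- sum(as.integer(shifted) != rd$cut_sites)
  cov <- atac_coverage(rd$reads, sim$genome)
  word <- canonical_label("gataag")
  prof <- footprint_profile(cov, sim$elements, word, sim$genome, W = W,
                            mode = "codeword")
  ctr <- mean(prof$mean[abs(prof$offset) <= 5])
  flank <- mean(prof$mean[abs(prof$offset) >= W / 2])
  ctrl <- footprint_profile(cov, sim$elements, word, sim$genome, W = W,
                            mode = "element-center")
  c0 <- ctrl$mean[ctrl$offset == 0]
  cf <- ctrl$mean[abs(ctrl$offset) >= W / 2]
  list(roundtrip_mismatches = mism,
       center_flank_ratio = ctr / flank,
       control_center_dev = abs(c0 - mean(cf)),
       control_band = 2 * sd(cf) + 2 * ctrl$band[ctrl$offset == 0],
       profile = prof, control = ctrl,
       n_anchors = attr(prof, "n_anchors"),
       n_reads = nrow(rd$reads))
}

#' Sliding-window scan experiment
#'
#' Trains an enhancer-vs-random and a tissue-discriminating classifier
#' on a synthetic two-tissue world, then scans a dedicated chromosome
#' holding exactly one planted brain-type element on an otherwise
#' motif-free background (chance occurrences of either consensus word
#' are scrubbed by point mutation). Checks that the brain-track argmax
#' window overlaps the planted element and that the combination rule
#' satisfies track_a + track_b = p1 exactly.
#'
#' @param seed Integer seed.
#' @param n_per_tissue Training elements per tissue.
#' @param q Feature-count target for both classifiers.
#' @return List with `track`, `element` (chrom/start/end of the planted
#'   element), `argmax_overlap` (0/1), `identity_max_err`, `best`.
#' @export
scan_experiment <- function(seed, n_per_tissue = 60L, q = 30L) {
  cfg <- synthetic_config(
    c("brain", "liver"), n_per_tissue, element_length = 200L,
    motif_per_tissue = c(brain = "cagatg", liver = "taaaca"),
    motif_mutation_prob = 0, sharing_prob = 0, seed = seed,
    n_chromosomes = 6L)
  sim <- generate_elements(cfg)
  space <- codeword_space(4L, 6L)
  opts <- klr_opts(max_epochs = 12, tol = 1e-6, path_epochs = 3,
                   max_bisect = 5, warn_nonconverged = FALSE)
  m_enh <- suppressWarnings(klr_leapfrog(
    build_dataset(enhancer_vs_random(sim$elements, sim$genome,
                                     seed = seed + 1L),
                  sim$genome, space, mode = "occurrence"), q, opts))
  m_ab <- suppressWarnings(klr_leapfrog(
    build_dataset(leaves_collection(sim$elements, "brain"),
                  sim$genome, space, mode = "occurrence"), q, opts))
  scan_chrom <- with_seed(seed + 2L, {
    bg <- scrub_chance_hits(
      paste(random_dna(20000L, cfg$background_gc), collapse = ""),
      c("cagatg", "taaaca"))
    pos <- 12000L + sample.int(195L, 1L) - 1L
    substr(bg, pos + 1L, pos + 6L) <- "cagatg"
    list(seq = bg, start = pos)
  })
  genome <- c(sim$genome, scan1 = scan_chrom$seq)
  tr <- scan_genome(genome, "scan1", m_enh, m_ab, space,
                    window = 400L, step = 100L)
  best <- tr[which.max(tr$track_a), ]
  el <- list(chrom = "scan1", start = scan_chrom$start,
             end = scan_chrom$start + 200L)
  overlap <- best$start < el$end && best$end > el$start
  list(track = tr, element = el,
       argmax_overlap = as.integer(overlap),
       identity_max_err = max(abs(tr$track_a + tr$track_b - tr$p1)),
       best = best, model_enh = m_enh, model_ab = m_ab)
}

#' Generative likelihood-ratio oracle for two-tissue synthetic elements
#'
#' Computes the exact log likelihood ratio of "element carries one
#' planted copy of motif A" versus "of motif B" under the synthetic
#' generative model: a uniform planting position, a random orientation,
#' independent per-position mutation with the given probability (to one
#' of the three other bases), and an order-0 background with the given
#' GC content. This is the Bayes-optimal discriminant for the
#' two-tissue recovery setting; no classifier on the same data can beat
#' its ranking in expectation, so its PR-AUC is the information ceiling
#' of the configuration.
#'
#' @param sequences Character vector of element sequences.
#' @param motif_a,motif_b Consensus words over \{a,c,g,t\}.
#' @param mutation Per-position mutation probability used when planting.
#' @param gc Background GC fraction.
#' @return Numeric vector of log likelihood-ratio scores (higher =
#'   more A-like).
#' @export
llr_oracle_scores <- function(sequences, motif_a, motif_b,
                              mutation = 0.1, gc = 0.41) {
  qbg <- c(a = (1 - gc) / 2, c = gc / 2, g = gc / 2, t = (1 - gc) / 2)
  win_weights <- function(ch, motif) {
    mm <- strsplit(motif, "")[[1L]]
    k <- length(mm)
    L <- length(ch)
    if (L < k) return(numeric(0))
    w <- rep(1, L - k + 1L)
    for (j in seq_len(k)) {
      cj <- ch[j:(L - k + j)]
      pr <- ifelse(cj == mm[j], 1 - mutation, mutation / 3)
      w <- w * pr / qbg[cj]
    }
    w
  }
  score_one <- function(s, motif) {
    ch <- strsplit(tolower(s), "")[[1L]]
    w <- c(win_weights(ch, motif),
           win_weights(ch, reverse_complement(motif)))
    log(mean(w))
  }
  vapply(sequences, function(s)
    score_one(s, motif_a) - score_one(s, motif_b), 0,
    USE.NAMES = FALSE)
}

# point-mutate the center of every occurrence (both orientations) of the
# given words until none remains
scrub_chance_hits <- function(seq, words) {
  pats <- unique(c(words, reverse_complement(words)))
  repeat {
    hit <- FALSE
    for (p in pats) {
      g <- gregexpr(p, seq, fixed = TRUE)[[1L]]
      if (g[1L] == -1L) next
      hit <- TRUE
      for (pos in g) {
        mid <- pos + nchar(p) %/% 2L
        old <- substr(seq, mid, mid)
        substr(seq, mid, mid) <- sample(setdiff(c("a", "c", "g", "t"),
                                                old), 1L)
      }
    }
    if (!hit) return(seq)
  }
}
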
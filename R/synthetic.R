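# Synthetic enhancer data with planted motifs: genomes, per-tissue
# activity, and ATAC-like reads with a protected footprint. Everything is
# deterministic given (config, seed); RNG state of the caller is restored.

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(c("a", "c", "g", "t"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Configuration of the synthetic enhancer generator
#'
#' Defines the study conditions emulated by the generator: several
#' tissues, elements active mostly in their source tissue (plus each
#' additional tissue independently with `sharing_prob`), one mutated
#' copy of each active tissue's consensus motif planted per element at a
#' uniform position (random orientation), order-0 background with
#' configurable GC, and ATAC-like cut sites depleted over the planted
#' motif of the element's source tissue.
#'
#' @param tissue_names Character vector of tissue identifiers.
#' @param n_elements_per_tissue Elements whose source is each tissue.
#' @param element_length Element width in bp (default 1000).
#' @param motif_per_tissue Named character vector / list mapping each
#'   tissue to a consensus word over \{a,c,g,t\} (length 6-8 typical).
#' @param motif_mutation_prob Per-position probability that a planted
#'   motif base is replaced by a different random base.
#' @param sharing_prob Probability that an element is also active in
#'   each additional tissue (independently).
#' @param background_gc Background GC fraction in (0, 1).
#' @param reads_per_element ATAC read pairs (as single-end reads)
#'   sampled per element.
#' @param footprint_halfwidth Half-width in bp of the protected window
#'   around the planted motif center.
#' @param footprint_depletion Multiplicative cut-site density inside the
#'   protected window (1 = no protection).
#' @param read_length Emitted read length in bp (only the 5' end is
#'   meaningful downstream).
#' @param read_flank Margin in bp around each element over which cut
#'   sites are also sampled, keeping aggregate profiles free of
#'   sampling-edge falloff (default 100).
#' @param n_chromosomes Number of synthetic autosome-like chromosomes.
#' @param chrom_length Length of each chromosome in bp; `NULL` sizes
#'   chromosomes automatically to 3x the packed element length (at
#'   least 50 kb).
#' @param chrm_length Length of the synthetic mitochondrial sequence.
#' @param chrm_words Optional words planted (unmutated) into chrM, to
#'   exercise the mitochondrial footprint control.
#' @param seed Integer seed; identical seed + config give byte-identical
#'   outputs.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(tissue_names, n_elements_per_tissue,
                             element_length = 1000L,
                             motif_per_tissue,
                             motif_mutation_prob = 0.1,
                             sharing_prob = 0.1,
                             background_gc = 0.41,
                             reads_per_element = 200L,
                             footprint_halfwidth = 10L,
                             footprint_depletion = 0.2,
                             read_length = 50L,
                             read_flank = 100L,
                             n_chromosomes = 19L,
                             chrom_length = NULL,
                             chrm_length = 16000L,
                             chrm_words = character(0),
                             seed = 1L) {
  motif_per_tissue <- vapply(motif_per_tissue, tolower, "")
  stopifnot(length(tissue_names) >= 1L,
            n_elements_per_tissue >= 1L,
            all(tissue_names %in% names(motif_per_tissue)),
            all(grepl("^[acgt]+$", motif_per_tissue)),
            motif_mutation_prob >= 0, motif_mutation_prob <= 1,
            sharing_prob >= 0, sharing_prob <= 1,
            background_gc > 0, background_gc < 1,
            footprint_depletion >= 0,
            element_length >= max(nchar(motif_per_tissue)))
  structure(list(tissue_names = tissue_names,
                 n_elements_per_tissue = as.integer(n_elements_per_tissue),
                 element_length = as.integer(element_length),
                 motif_per_tissue = motif_per_tissue,
                 motif_mutation_prob = motif_mutation_prob,
                 sharing_prob = sharing_prob,
                 background_gc = background_gc,
                 reads_per_element = as.integer(reads_per_element),
                 footprint_halfwidth = as.integer(footprint_halfwidth),
                 footprint_depletion = footprint_depletion,
                 read_length = as.integer(read_length),
                 read_flank = as.integer(read_flank),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = chrom_length,
                 chrm_length = as.integer(chrm_length),
                 chrm_words = tolower(chrm_words),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

mutate_motif <- function(word, prob) {
  ch <- strsplit(word, "")[[1L]]
  hit <- runif(length(ch)) < prob
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("a", "c", "g", "t"), b), 1L), "")
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic genome with planted enhancer elements
#'
#' Elements are placed non-overlapping on synthetic chromosomes; each
#' element's activity set contains its source tissue plus every other
#' tissue independently with `sharing_prob`, and one mutated copy of
#' each active tissue's motif is planted at a uniform position in a
#' random orientation. A short chrM sequence (with optional planted
#' words) is always included. All coordinates 0-based half-open.
#'
#' @param config A [synthetic_config()].
#' @return A list with `genome` (named character vector of chromosome
#'   sequences), `elements` (an [element_table()]), and `planted` (a
#'   data.frame of planted motif copies: `id`, `tissue`, `chrom`,
#'   `start`, `center`, `strand`, `primary`).
#' @export
generate_elements <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_elements_impl(config))
}

generate_elements_impl <- function(cfg) {
  tis <- cfg$tissue_names
  L <- cfg$element_length
  N <- length(tis) * cfg$n_elements_per_tissue
  source_tissue <- rep(tis, each = cfg$n_elements_per_tissue)
  # spread elements over chromosomes round-robin
  chrom_of <- rep_len(seq_len(cfg$n_chromosomes), N)
  per_chrom <- tabulate(chrom_of, cfg$n_chromosomes)
  clen <- cfg$chrom_length
  if (is.null(clen)) clen <- max(50000L, 3L * max(per_chrom) * L)
  clen <- as.integer(clen)
  if (any(per_chrom * L > clen))
    stop("elements do not fit on the requested genome size")
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))

  genome <- vector("list", cfg$n_chromosomes)
  starts <- integer(N); ends <- integer(N); chroms <- character(N)
  idx_by_chrom <- split(seq_len(N), chrom_of)
  for (ci in seq_len(cfg$n_chromosomes)) {
    seqv <- random_dna(clen, cfg$background_gc)
    els <- idx_by_chrom[[as.character(ci)]]
    if (!is.null(els) && length(els)) {
      nc <- length(els)
      free <- clen - nc * L
      off <- sort(sample.int(free + 1L, nc, replace = TRUE) - 1L)
      st <- off + (seq_len(nc) - 1L) * L
      starts[els] <- st; ends[els] <- st + L; chroms[els] <- chrom_names[ci]
    }
    genome[[ci]] <- seqv
  }

  # activity sets and planted motifs
  ids <- sprintf("e%05d", seq_len(N))
  activity <- vector("list", N)
  pl_id <- character(0); pl_t <- character(0); pl_chr <- character(0)
  pl_start <- integer(0); pl_strand <- character(0); pl_prim <- logical(0)
  for (e in seq_len(N)) {
    src <- source_tissue[e]
    others <- setdiff(tis, src)
    extra <- others[runif(length(others)) < cfg$sharing_prob]
    act <- c(src, extra)
    activity[[e]] <- act
    ci <- chrom_of[e]
    occupied_lo <- integer(0); occupied_hi <- integer(0)
    for (t in act) {
      motif <- mutate_motif(cfg$motif_per_tissue[[t]],
                            cfg$motif_mutation_prob)
      if (runif(1) < 0.5) motif <- reverse_complement(motif)
      wl <- nchar(motif)
      # keep multiple planted copies from overwriting each other
      for (try in 1:100) {
        pos <- sample.int(L - wl + 1L, 1L) - 1L
        if (!any(pos < occupied_hi & pos + wl > occupied_lo)) break
      }
      occupied_lo <- c(occupied_lo, pos)
      occupied_hi <- c(occupied_hi, pos + wl)
      g0 <- starts[e] + pos
      genome[[ci]][(g0 + 1L):(g0 + wl)] <- strsplit(motif, "")[[1L]]
      pl_id <- c(pl_id, ids[e]); pl_t <- c(pl_t, t)
      pl_chr <- c(pl_chr, chroms[e]); pl_start <- c(pl_start, g0)
      pl_strand <- c(pl_strand,
                     if (motif == cfg$motif_per_tissue[[t]]) "+" else "*")
      pl_prim <- c(pl_prim, t == src)
    }
  }

  chrm <- random_dna(cfg$chrm_length, cfg$background_gc)
  for (w in cfg$chrm_words) {
    wl <- nchar(w)
    pos <- sample.int(cfg$chrm_length - wl + 1L, 1L) - 1L
    chrm[(pos + 1L):(pos + wl)] <- strsplit(w, "")[[1L]]
  }
  genome_chr <- vapply(genome, paste, "", collapse = "")
  names(genome_chr) <- chrom_names
  genome_chr[["chrM"]] <- paste(chrm, collapse = "")

  wl_all <- nchar(cfg$motif_per_tissue[pl_t])
  planted <- data.frame(id = pl_id, tissue = pl_t, chrom = pl_chr,
                        start = pl_start,
                        center = pl_start + (wl_all - 1L) %/% 2L,
                        strand = pl_strand, primary = pl_prim,
                        stringsAsFactors = FALSE)
  elements <- element_table(
    data.frame(chrom = chroms, start = starts, end = ends, id = ids,
               stringsAsFactors = FALSE),
    tissues = activity, element_width = L)
  ord <- order(match(elements$chrom, chrom_names), elements$start)
  elements <- elements[ord, ]
  attr(elements, "element_width") <- L
  list(genome = genome_chr, elements = elements, planted = planted)
}

#' Generate ATAC-like reads with a protected footprint
#'
#' Cut sites are sampled per element with density multiplied by
#' `footprint_depletion` within `footprint_halfwidth` bp of the planted
#' motif center of the element's source tissue (elements without a
#' planted record are sampled uniformly). Each cut site is emitted as a
#' fixed-length strand-labeled read whose 5' end is offset by -4
#' (forward) or +5 (reverse) from the cut site, so applying the Tn5
#' shift (+4 forward / -5 reverse) recovers the cut site exactly.
#'
#' @param config A [synthetic_config()].
#' @param elements The [element_table()] from [generate_elements()].
#' @param planted The `planted` data.frame from [generate_elements()].
#' @param depletion Override of `config$footprint_depletion` (optional).
#' @return A list with `reads` (BED6-style data.frame: chrom, start,
#'   end, name, score, strand) and `cut_sites` (integer vector of the
#'   sampled cut-site coordinates, aligned with the read rows).
#' @export
generate_atac_reads <- function(config, elements, planted,
                                depletion = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(depletion)) depletion <- config$footprint_depletion
  with_seed(config$seed + 1L,
            generate_atac_reads_impl(config, elements, planted, depletion))
}

generate_atac_reads_impl <- function(cfg, elements, planted, depletion) {
  R <- cfg$reads_per_element
  if (R <= 0L)
    return(list(reads = data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0), name = character(0),
                                   score = integer(0), strand = character(0),
                                   stringsAsFactors = FALSE),
                cut_sites = integer(0)))
  prim <- planted[planted$primary, , drop = FALSE]
  center_of <- setNames(prim$center, prim$id)
  L <- cfg$element_length
  hw <- cfg$footprint_halfwidth
  pad <- cfg$read_flank
  n <- nrow(elements)
  chrom <- character(n * R); cut <- integer(n * R); strand <- character(n * R)
  k <- 0L
  for (e in seq_len(n)) {
    # cut sites cover the element plus a flank margin, so aggregate
    # profiles are not confounded by sampling-edge falloff
    p0 <- max(0L, elements$start[e] - pad)
    p1 <- elements$end[e] + pad
    span <- p1 - p0
    wts <- rep(1, span)
    ctr <- center_of[elements$id[e]]
    if (!is.na(ctr)) {
      rel <- ctr - p0
      lo <- max(1L, rel - hw + 1L); hi <- min(span, rel + hw + 1L)
      wts[lo:hi] <- depletion
    }
    cs <- p0 + sample.int(span, R, replace = TRUE, prob = wts) - 1L
    idx <- k + seq_len(R)
    chrom[idx] <- elements$chrom[e]
    cut[idx] <- cs
    strand[idx] <- ifelse(runif(R) < 0.5, "+", "-")
    k <- k + R
  }
  fw <- strand == "+"
  start <- ifelse(fw, cut - 4L, cut + 6L - cfg$read_length)
  end <- start + cfg$read_length
  reads <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(end),
                      name = sprintf("r%07d", seq_along(cut)),
                      score = 0L, strand = strand,
                      stringsAsFactors = FALSE)
  list(reads = reads, cut_sites = cut)
}

#' Uniform random genomic regions
#'
#' Samples `n` intervals of exactly `length` bp uniformly from the
#' genome, with no genomic region excluded. Chromosomes are chosen with
#' probability proportional to the number of valid start positions.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param n Number of regions.
#' @param length Region width in bp.
#' @param seed Integer seed.
#' @return data.frame with `chrom`, `start`, `end`, `id` (0-based
#'   half-open).
#' @export
generate_random_regions <- function(genome, n, length, seed = 1L) {
  slots <- pmax(nchar(genome) - length + 1L, 0L)
  if (all(slots == 0L)) stop("genome shorter than the requested length")
  if (n == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), id = character(0),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    ci <- sample.int(length(genome), n, replace = TRUE, prob = slots)
    st <- vapply(ci, function(i) sample.int(slots[i], 1L) - 1L, 0L)
    data.frame(chrom = names(genome)[ci], start = st, end = st + length,
               id = sprintf("r%05d", seq_len(n)), stringsAsFactors = FALSE)
  })
}

#' Write a synthetic data set to disk
#'
#' Emits the genome (FASTA), one BED4 file per tissue, an activity TSV
#' (element id, comma-separated tissue list), reads as BED6, and a JSON
#' manifest of planted motif positions. All coordinates 0-based
#' half-open.
#'
#' @param sim Output of [generate_elements()].
#' @param reads Optional output of [generate_atac_reads()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir, reads = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- Biostrings::DNAStringSet(toupper(sim$genome))
  names(gen) <- names(sim$genome)
  Biostrings::writeXStringSet(gen, file.path(dir, "genome.fa"))
  el <- sim$elements
  for (t in unique(unlist(el$tissues))) {
    keep <- vapply(el$tissues, function(a) t %in% a, TRUE)
    write_bed(el[keep, c("chrom", "start", "end", "id")],
              file.path(dir, paste0(t, ".bed")))
  }
  act <- data.frame(id = el$id,
                    tissues = vapply(el$tissues, paste, "", collapse = ","))
  write.table(act, file.path(dir, "activity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$planted, file.path(dir, "planted.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(reads))
    write_bed(reads$reads, file.path(dir, "reads.bed"))
  invisible(dir)
}
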
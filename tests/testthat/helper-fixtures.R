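# Shared fixtures and independent oracles used across test files.

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("a", "c", "g", "t"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc_string <- function(s) {
  # independent of the package's reverse_complement
  map <- c(a = "t", c = "g", g = "c", t = "a", n = "n")
  paste(rev(map[strsplit(tolower(s), "")[[1]]]), collapse = "")
}

# brute-force enumeration oracle: all canonical labels for a single k
brute_space_k <- function(k) {
  alph <- c("a", "c", "g", "n", "t")
  ends <- c("a", "c", "g", "t")
  grids <- c(list(ends), rep(list(alph), k - 2), list(ends))
  pats <- do.call(paste0, expand.grid(grids[length(grids):1])[, length(grids):1])
  pats <- sort(unique(pats), method = "radix")
  labs <- unique(vapply(pats, function(p) {
    q <- rc_string(p)
    pair <- sort(c(p, q), method = "radix")
    paste0(pair[1], "|", if (p == q) p else pair[2])
  }, "", USE.NAMES = FALSE))
  sort(labs, method = "radix")
}

# brute-force feature counter: scan every window against every pattern
brute_count <- function(seqs, k_min, k_max) {
  out <- list()
  for (s in seqs) {
    ch <- strsplit(tolower(s), "")[[1]]
    counts <- new.env()
    for (k in k_min:k_max) {
      if (length(ch) < k) next
      for (pos in seq_len(length(ch) - k + 1)) {
        win <- ch[pos:(pos + k - 1)]
        if (any(!win %in% c("a", "c", "g", "t"))) next
        interior <- if (k > 2) 2:(k - 1) else integer(0)
        for (msk in 0:(2^length(interior) - 1)) {
          pat <- win
          gaps <- interior[bitwAnd(msk, 2^(seq_along(interior) - 1)) > 0]
          pat[gaps] <- "n"
          p <- paste(pat, collapse = "")
          q <- rc_string(p)
          pair <- sort(c(p, q), method = "radix")
          lab <- paste0(pair[1], "|", if (p == q) p else pair[2])
          counts[[lab]] <- (counts[[lab]] %||% 0) + 1
        }
      }
    }
    out[[s]] <- unlist(as.list(counts))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small dense random classification instance; label noise keeps the
# unpenalized MLE finite
toy_instance <- function(seed, n = 40, m = 8, unbalanced = FALSE,
                         flip = 0) {
  set.seed(seed)
  x <- Matrix::Matrix(rbinom(n * m, 3, 0.3), n, m, sparse = TRUE)
  beta <- c(rnorm(3, sd = 1.2), rep(0, m - 3))
  z <- as.numeric(x %*% beta) + if (unbalanced) -1 else 0.2
  y <- rbinom(n, 1, plogis(z))
  if (flip > 0) {
    sw <- runif(n) < flip
    y[sw] <- 1 - y[sw]
  }
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  klr_dataset(x, y, mode = "occurrence")
}

# remove every chance occurrence of the given motifs (both orientations)
# from a sequence by point-mutating hit centers; used to build scan
# chromosomes where a planted element is the unique signal source
scrub_motifs <- function(seq, motifs) {
  pats <- unique(c(motifs, vapply(motifs, rc_string, "")))
  repeat {
    hit <- FALSE
    for (p in pats) {
      g <- gregexpr(p, seq, fixed = TRUE)[[1]]
      if (g[1] == -1) next
      hit <- TRUE
      for (pos in g) {
        mid <- pos + nchar(p) %/% 2
        old <- substr(seq, mid, mid)
        substr(seq, mid, mid) <- sample(setdiff(c("a", "c", "g", "t"),
                                                old), 1)
      }
    }
    if (!hit) return(seq)
  }
}

# compact two-tissue synthetic scenario used by several modules
small_sim <- function(seed = 3, n_per = 40, L = 200, mu = 0,
                      sharing = 0.15, reads = 100, depletion = 0.2,
                      hw = 10) {
  cfg <- synthetic_config(
    c("liver", "lung"), n_per, element_length = L,
    motif_per_tissue = c(liver = "gataag", lung = "taaaca"),
    motif_mutation_prob = mu, sharing_prob = sharing,
    reads_per_element = reads, footprint_halfwidth = hw,
    footprint_depletion = depletion, seed = seed)
  c(list(config = cfg), generate_elements(cfg))
}
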
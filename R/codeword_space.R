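#' Reverse complement of a gapped pattern
#'
#' Complements a pattern over the alphabet \{a,c,g,t,n\} (a<->t, c<->g,
#' n<->n, where 'n' is the gap/wildcard) and reverses it.
#'
#' @param pattern Character vector of patterns over \{a,c,g,t,n\}
#'   (case-insensitive).
#' @return Character vector of reverse-complemented patterns (lower case).
#' @examples
#' reverse_complement("anntg")  # "cannt"
#' reverse_complement("cttatc") # "gataag"
#' @export
reverse_complement <- function(pattern) {
  pattern <- tolower(pattern)
  bad <- grepl("[^acgtn]", pattern)
  if (any(bad))
    stop("invalid character in pattern(s): ",
         paste(pattern[bad], collapse = ", "))
  comp <- chartr("acgtn", "tgcan", pattern)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Canonical code-word label of a gapped pattern
#'
#' A code word is the equivalence class of a pattern and its reverse
#' complement, labeled `"p|q"` where `p <= q` in lexicographic order
#' under the alphabet a < c < g < n < t. Palindromic patterns are labeled
#' `"p|p"`. The first and last character must be a concrete base.
#'
#' @param pattern Character vector of gapped patterns.
#' @return Character vector of canonical labels.
#' @examples
#' canonical_label("gataag") # "cttatc|gataag"
#' canonical_label("cannt")  # "anntg|cannt"
#' @export
canonical_label <- function(pattern) {
  pattern <- tolower(pattern)
  if (any(grepl("^n|n$", pattern)))
    stop("gap character 'n' not allowed at pattern ends")
  rc <- reverse_complement(pattern)
  a <- character(length(pattern))
  # lexicographic order with a<c<g<n<t equals byte order of these letters
  smaller <- mapply(function(p, q) {
    v <- sort(c(p, q), method = "radix")[1L]
    v
  }, pattern, rc, USE.NAMES = FALSE)
  larger <- ifelse(smaller == pattern, rc, pattern)
  paste0(smaller, "|", ifelse(pattern == rc, pattern, larger))
}

#' Enumerate the canonical gapped code-word feature space
#'
#' Enumerates all k-mers of lengths `k_min` to `k_max` with concrete
#' bases at both ends and any of \{a,c,g,t,n\} at interior positions
#' ('n' denotes a gap matching any base), collapsed by reverse
#' complement. Columns are ordered by length, then label. For the
#' default range 4..8 the space has m = 156,570 code words.
#'
#' @param k_min,k_max Integer word-length range, `1 <= k_min <= k_max`.
#' @return An object of class `codeword_space` with elements `k_min`,
#'   `k_max`, `labels` (ordered canonical labels), `m` (total feature
#'   count), `per_k` (features per length) and internal lookup tables
#'   used by [featurize()].
#' @examples
#' sp <- codeword_space(4, 4)
#' sp$m  # 210
#' @export
codeword_space <- function(k_min = 4L, k_max = 8L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  stopifnot(k_min >= 1L, k_min <= k_max, k_max <= 10L)
  enc <- cw_enumerate_cpp(k_min, k_max)
  structure(list(k_min = k_min, k_max = k_max,
                 labels = enc$labels, m = enc$m,
                 per_k = setNames(enc$per_k, k_min:k_max),
                 lookups = enc$lookups),
            class = "codeword_space")
}

#' @export
print.codeword_space <- function(x, ...) {
  cat(sprintf("codeword_space: k = %d..%d, m = %d canonical code words\n",
              x$k_min, x$k_max, x$m))
  invisible(x)
}

#' Closed-form size of the code-word space
#'
#' Per length k there are 16 * 5^(k-2) patterns with concrete ends;
#' palindromes number 4 * 5^(k/2 - 1) for even k and 4 * 5^((k-3)/2) for
#' odd k (the middle position of an odd palindrome must be 'n'). The
#' canonical count is (patterns + palindromes) / 2.
#'
#' @param k_min,k_max Integer word-length range (k >= 2).
#' @return Named integer vector of canonical counts per length.
#' @export
codeword_space_size <- function(k_min = 4L, k_max = 8L) {
  ks <- k_min:k_max
  stopifnot(all(ks >= 2))
  patterns <- 16 * 5^(ks - 2)
  pal <- ifelse(ks %% 2 == 0, 4 * 5^(ks / 2 - 1), 4 * 5^((ks - 3) / 2))
  setNames(as.integer((patterns + pal) / 2), ks)
}
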
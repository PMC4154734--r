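# Independent brute-force oracles for the digest machinery. These scan
# naively, position by position, with no shared code with the package
# internals.

oracle_find_sites <- function(seq, pattern) {
  L <- nchar(seq); k <- nchar(pattern)
  if (L < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(L - k + 1L)) {
    if (substr(seq, i, i + k - 1L) == pattern) hits <- c(hits, i - 1L)
  }
  hits
}

# All fragments between consecutive recognition-site matches of either
# pattern, labelled by end enzymes; 0-based half-open from left site
# start to right site end.
oracle_fragments <- function(seq, patA, patB) {
  sa <- oracle_find_sites(seq, patA)
  sb <- oracle_find_sites(seq, patB)
  sites <- rbind(
    if (length(sa)) data.frame(pos = sa, len = nchar(patA), enz = "A"),
    if (length(sb)) data.frame(pos = sb, len = nchar(patB), enz = "B")
  )
  if (is.null(sites) || nrow(sites) < 2L) {
    return(data.frame(start = integer(0), end = integer(0),
                      left = character(0), right = character(0)))
  }
  sites <- sites[order(sites$pos, sites$pos + sites$len), ]
  n <- nrow(sites)
  data.frame(
    start = sites$pos[-n],
    end = sites$pos[-1] + sites$len[-1],
    left = sites$enz[-n],
    right = sites$enz[-1]
  )
}

oracle_ab_loci <- function(seq, patA, patB, min_bp, max_bp) {
  fr <- oracle_fragments(seq, patA, patB)
  fr$length <- fr$end - fr$start
  ab <- fr[((fr$left == "A" & fr$right == "B") |
              (fr$left == "B" & fr$right == "A")) &
             fr$length >= min_bp & fr$length <= max_bp, , drop = FALSE]
  if (nrow(ab) == 0L) return(ab)
  ab$orientation <- ifelse(ab$left == "A", "+", "-")
  ab[order(ab$start), c("start", "end", "length", "orientation")]
}

rc_chars <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
oracle_revcomp <- function(s) {
  paste(rev(rc_chars[strsplit(s, "")[[1]]]), collapse = "")
}

# random genome with injected recognition sites so fragments exist
random_site_genome <- function(len, n_sites = 8L) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  pats <- c("CCTGCAGG", "GAATTC")
  for (k in seq_len(n_sites)) {
    p <- pats[1L + (k %% 2L)]
    at <- sample(len - nchar(p), 1L)
    bases[at:(at + nchar(p) - 1L)] <- strsplit(p, "")[[1]]
  }
  paste(bases, collapse = "")
}

# exhaustive sum-of-pairs MSA oracle for three tiny sequences
# (linear gap penalty). Returns best score and the column count of an
# optimal alignment (ties resolved toward fewer columns).
oracle_msa3 <- function(s1, s2, s3, match = 1, mismatch = -1, gap = -1) {
  x <- strsplit(s1, "")[[1]]; y <- strsplit(s2, "")[[1]]; z <- strsplit(s3, "")[[1]]
  n1 <- length(x); n2 <- length(y); n3 <- length(z)
  sc <- function(a, b) {
    if (is.na(a) && is.na(b)) return(0)
    if (is.na(a) || is.na(b)) return(gap)
    if (a == b) match else mismatch
  }
  best <- array(-Inf, dim = c(n1 + 1L, n2 + 1L, n3 + 1L))
  cols <- array(Inf, dim = dim(best))
  best[1, 1, 1] <- 0; cols[1, 1, 1] <- 0
  moves <- expand.grid(d1 = 0:1, d2 = 0:1, d3 = 0:1)
  moves <- moves[rowSums(moves) > 0L, ]
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    if (i + j + k == 0L) next
    for (m in seq_len(nrow(moves))) {
      d <- moves[m, ]
      pi <- i - d$d1; pj <- j - d$d2; pk <- k - d$d3
      if (pi < 0 || pj < 0 || pk < 0) next
      a <- if (d$d1) x[i] else NA
      b <- if (d$d2) y[j] else NA
      cc <- if (d$d3) z[k] else NA
      s <- best[pi + 1, pj + 1, pk + 1] + sc(a, b) + sc(a, cc) + sc(b, cc)
      if (s > best[i + 1, j + 1, k + 1] ||
          (s == best[i + 1, j + 1, k + 1] &&
             cols[pi + 1, pj + 1, pk + 1] + 1 < cols[i + 1, j + 1, k + 1])) {
        best[i + 1, j + 1, k + 1] <- s
        cols[i + 1, j + 1, k + 1] <- cols[pi + 1, pj + 1, pk + 1] + 1
      }
    }
  }
  list(score = best[n1 + 1, n2 + 1, n3 + 1],
       ncol = cols[n1 + 1, n2 + 1, n3 + 1])
}
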
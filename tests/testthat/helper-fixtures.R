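# Shared fixtures and independent oracles used across test files.
# Oracles are deliberately written with different machinery than the
# implementation they check (Biostrings matching, enumeration, O(n^2) loops).

# A tiny two-position variable set over the real template (diversity 4).
toy_varset <- function(template = kras_codon_template()) {
  variable_position_set(c(2L, 26L),
                        list(c("ACT", "ACC"), c("AAT", "AAC")),
                        template)
}

# Independent anchored-trimming oracle: leftmost minimal-mismatch window of
# `anchor` in each read, mismatches counted by Biostrings::neditStartingAt.
oracle_trim <- function(reads, a5, a3, rate = 0.2) {
  mm_scan <- function(read, anchor) {
    L <- nchar(anchor)
    if (nchar(read) < L) return(NULL)
    ed <- Biostrings::neditStartingAt(Biostrings::DNAString(anchor),
                                      Biostrings::DNAString(read),
                                      starting.at = 1:(nchar(read) - L + 1),
                                      with.indels = FALSE)
    best <- min(ed)
    if (best > floor(rate * L)) return(NULL)
    which(ed == best)[1] - 1L   # leftmost best, 0-based
  }
  vapply(reads, function(rd) {
    off5 <- mm_scan(rd, a5)
    if (is.null(off5)) return(NA_character_)
    payload <- substring(rd, off5 + nchar(a5) + 1L)
    if (!nzchar(payload)) return(NA_character_)
    off3 <- mm_scan(payload, a3)
    if (!is.null(off3)) payload <- substring(payload, 1L, off3)
    if (!nzchar(payload)) NA_character_ else payload
  }, "", USE.NAMES = FALSE)
}

# Brute-force barcode-merging oracle. Fixed order by (-count, name); a
# barcode survives iff no surviving earlier barcode lies within distance;
# each absorbed barcode donates its count to the first surviving earlier
# barcode within distance.
oracle_merge <- function(counts, max_distance = 3) {
  ids <- names(counts)
  ord <- order(-counts, ids)
  d <- utils::adist(ids, ids)
  survives <- logical(length(ids))
  donate_to <- rep(NA_integer_, length(ids))
  for (k in seq_along(ord)) {
    i <- ord[k]
    host <- NA_integer_
    if (k > 1L) {
      earlier <- ord[seq_len(k - 1L)]
      cand <- earlier[survives[earlier] & d[i, earlier] < max_distance]
      if (length(cand)) host <- cand[1]
    }
    if (is.na(host)) survives[i] <- TRUE else donate_to[i] <- host
  }
  out <- counts[survives]
  for (i in which(!survives)) {
    nm <- ids[donate_to[i]]
    out[nm] <- out[nm] + counts[i]
  }
  out
}

# Brute-force two-sided Fisher oracle: enumerate all tables with the observed
# margins and sum the exact hypergeometric probabilities (factorial form) of
# tables no more probable than the observed one.
oracle_fisher <- function(a, b, c, d) {
  lfac <- function(x) lgamma(x + 1)
  tab_prob <- function(a2) {
    b2 <- a + b - a2; c2 <- a + c - a2; d2 <- d - a + a2
    exp(lfac(a + b) + lfac(c + d) + lfac(a + c) + lfac(b + d) -
          lfac(a + b + c + d) - lfac(a2) - lfac(b2) - lfac(c2) - lfac(d2))
  }
  lo <- max(0, a - d); hi <- min(a + b, a + c)
  support <- lo:hi
  probs <- vapply(support, tab_prob, 0)
  p_obs <- tab_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force TSS gap oracle: count integer positions strictly between the
# TSS base and the region's covered bases, by enumeration.
oracle_tss_gap <- function(s, e, t) {
  region <- s:(e - 1)
  if (t %in% region) return(0)
  between <- if (t > max(region)) (max(region) + 1):(t - 1) else (t + 1):(min(region) - 1)
  if (t == max(region) + 1 || t == min(region) - 1) 0 else length(between)
}

# Brute-force k-mer mappability oracle via Biostrings pattern counting:
# a 0-based start is mappable iff its k-mer occurs exactly once in the
# genome counting both strands.
oracle_mappable <- function(genome, k) {
  subjects <- Biostrings::DNAStringSet(genome)
  lapply(names(genome), function(ch) {
    L <- nchar(genome[[ch]])
    starts <- 1:(L - k + 1)
    kmers <- substring(genome[[ch]], starts, starts + k - 1)
    pd <- Biostrings::PDict(unique(kmers))
    fwd <- rowSums(vapply(seq_along(subjects), function(i) {
      Biostrings::countPDict(pd, subjects[[i]])
    }, integer(length(pd))))
    rev <- rowSums(vapply(seq_along(subjects), function(i) {
      Biostrings::countPDict(pd, Biostrings::reverseComplement(subjects[[i]]))
    }, integer(length(pd))))
    total <- (fwd + rev)[match(kmers, unique(kmers))]
    which(total == 1L) - 1L
  })
}

# Simulated tumors used by several files
small_alleles <- function(n = 6, seed = 42) sample_alleles(n = n, seed = seed)
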
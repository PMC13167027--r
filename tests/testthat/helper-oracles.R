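# Independent oracles and small fixture builders.  Everything here is kept
# deliberately naive (per-base loops, exhaustive enumeration, hand-rolled
# step-up) so it cannot share a code path with the implementation.

make_aln <- function(pos, cigar, read_id = paste0("r", seq_along(pos)),
                     ref_id = "ref1", flag = 0L, mapq = 60L) {
  data.table::data.table(read_id = read_id, flag = as.integer(flag),
                         ref_id = ref_id, pos = as.integer(pos),
                         mapq = as.integer(mapq), cigar = cigar)
}

# position-by-position depth recount walking each CIGAR with a cursor
brute_force_depth <- function(alignments, reference_length) {
  depth <- integer(reference_length)
  for (i in seq_len(nrow(alignments))) {
    ops <- regmatches(alignments$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", alignments$cigar[i]))[[1]]
    cursor <- alignments$pos[i]  # 0-based
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      kind <- substring(op, nchar(op))
      if (kind %in% c("M", "=", "X")) {
        depth[(cursor + 1):(cursor + len)] <- depth[(cursor + 1):(cursor + len)] + 1L
        cursor <- cursor + len
      } else if (kind %in% c("D", "N")) {
        cursor <- cursor + len
      }
      # I, S, H, P consume no reference
    }
  }
  depth
}

# total reference-consuming aligned bases of M/=/X operations
brute_force_aligned_bases <- function(alignments) {
  total <- 0L
  for (i in seq_len(nrow(alignments))) {
    ops <- regmatches(alignments$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", alignments$cigar[i]))[[1]]
    for (op in ops) {
      kind <- substring(op, nchar(op))
      if (kind %in% c("M", "=", "X")) {
        total <- total + as.integer(sub("[A-Z=]$", "", op))
      }
    }
  }
  total
}

# exhaustive two-sided Fisher p by enumeration over fixed-margin tables;
# point probabilities are exact ratios of binomial coefficients (all values
# integer-exact in doubles for totals <= 30)
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, support) * choose(r2, c1 - support) / choose(r1 + r2, c1)
  p_obs <- prob[a - support[1] + 1]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up written directly from the definition
bh_manual <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# random alignment table with mixed CIGARs over a small reference
random_alignments <- function(ref_len, n_reads) {
  if (n_reads == 0) return(make_aln(integer(0), character(0)))
  cigars <- character(n_reads)
  pos <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    n_ops <- sample(1:4, 1)
    kinds <- sample(c("M", "D", "I", "S"), n_ops, replace = TRUE)
    kinds[sample(n_ops, 1)] <- "M"      # at least one aligned block
    lens <- sample(1:30, n_ops, replace = TRUE)
    ref_span <- sum(lens[kinds %in% c("M", "D")])
    if (ref_span >= ref_len) {
      kinds <- "M"; lens <- sample(1:min(30, ref_len), 1); ref_span <- lens
    }
    pos[i] <- sample(0:(ref_len - ref_span), 1)
    cigars[i] <- paste0(lens, kinds, collapse = "")
  }
  make_aln(pos, cigars)
}

# small asv_table fixture
make_asv_table <- function(counts, taxonomy = NULL, compartment = "gill") {
  if (is.null(taxonomy)) {
    taxonomy <- stats::setNames(rep("Bacteria;TestPhylum", ncol(counts)),
                                colnames(counts))
  }
  meta <- data.frame(sample_id = rownames(counts), site = "site_A",
                     date = "2021-08",
                     compartment = rep(compartment, length.out = nrow(counts)))
  asv_table(counts, taxonomy, meta)
}
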
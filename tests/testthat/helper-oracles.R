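# Independent brute-force implementations used as oracles. These deliberately
# share no code path with the package: per-site loops, per-position set
# expansion, and whole-sequence translation instead of interval arithmetic
# and single-codon extraction.

# Per-site bin assignment by linear scan over bins.
oracle_bin_counts <- function(pos, hom, chrom_len, bin_size) {
  n_bins <- ceiling(chrom_len / bin_size)
  n <- integer(n_bins)
  h <- integer(n_bins)
  for (i in seq_along(pos)) {
    for (b in seq_len(n_bins)) {
      lo <- (b - 1) * bin_size
      hi <- min(b * bin_size, chrom_len)
      if (pos[i] >= lo && pos[i] < hi) {
        n[b] <- n[b] + 1L
        if (hom[i]) h[b] <- h[b] + 1L
        break
      }
    }
  }
  list(n = n, h = h)
}

# Windowed mean with explicit loops and NA skipping.
oracle_smooth <- function(d, w, include_center = TRUE) {
  n <- length(d)
  s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    acc <- 0; k <- 0
    for (j in seq.int(i - w, i + w)) {
      if (j < 1 || j > n) next
      if (!include_center && j == i) next
      if (is.na(d[j])) next
      acc <- acc + d[j]; k <- k + 1
    }
    if (k > 0) s[i] <- acc / k
  }
  s
}

# Threshold run extraction by a manual state machine.
oracle_runs <- function(s, tau) {
  runs <- list()
  open <- NA
  for (i in seq_along(s)) {
    hit <- !is.na(s[i]) && s[i] >= tau
    if (hit && is.na(open)) open <- i
    if (!hit && !is.na(open)) {
      runs[[length(runs) + 1]] <- c(open, i - 1)
      open <- NA
    }
  }
  if (!is.na(open)) runs[[length(runs) + 1]] <- c(open, length(s))
  runs
}

# Quadratic all-pairs interval intersection (0-based half-open).
oracle_intersections <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      lo <- max(a$start[i], b$start[j])
      hi <- min(a$end[i], b$end[j])
      if (lo < hi) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = a$chrom[i], start = lo, end = hi,
          a_start = a$start[i], a_end = a$end[i],
          b_start = b$start[j], b_end = b$end[j]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0)))
  }
  dplyr::bind_rows(out)
}

# Quadratic breed-specificity labels.
oracle_specific <- function(rohs) {
  spec <- rep(TRUE, nrow(rohs))
  for (i in seq_len(nrow(rohs))) {
    for (j in seq_len(nrow(rohs))) {
      if (i == j) next
      if (rohs$breed[i] == rohs$breed[j]) next
      if (rohs$platform[i] != rohs$platform[j]) next
      if (rohs$chrom[i] != rohs$chrom[j]) next
      if (max(rohs$start[i], rohs$start[j]) < min(rohs$end[i], rohs$end[j])) {
        spec[i] <- FALSE
      }
    }
  }
  spec
}

# Whole-CDS translation oracle for SNP consequences: expands every annotated
# position of the gene into labelled sets and, for coding positions,
# translates the entire reference and mutant CDS with Biostrings.
oracle_classify_snp <- function(chrom, pos, ref, alt, gene, genome) {
  if (chrom != gene$chrom) return("intergenic")
  ex <- gene$exons[[1]]
  span <- c(min(ex$start), max(ex$end))
  if (pos < span[1] || pos >= span[2]) return("intergenic")

  exon_set <- integer(0)
  for (j in seq_len(nrow(ex))) {
    exon_set <- c(exon_set, seq.int(ex$start[j], ex$end[j] - 1))
  }
  cds <- gene$cds[[1]]
  cds_set <- integer(0)
  for (j in seq_len(nrow(cds))) {
    cds_set <- c(cds_set, seq.int(cds$start[j], cds$end[j] - 1))
  }
  splice_set <- integer(0)
  if (nrow(ex) > 1) {
    for (j in seq_len(nrow(ex) - 1)) {
      a <- ex$end[j]; b <- ex$start[j + 1]
      splice_set <- c(splice_set, a, a + 1, b - 2, b - 1)
    }
  }

  if (pos %in% cds_set) {
    seqchr <- genome$sequences[[chrom]]
    mut <- seqchr
    substr(mut, pos + 1, pos + 1) <- alt
    cds_sorted <- sort(cds_set)
    get_cds <- function(s) {
      bases <- paste(vapply(cds_sorted, function(p) substr(s, p + 1, p + 1),
                            character(1)), collapse = "")
      dna <- Biostrings::DNAString(bases)
      if (gene$strand == "-") dna <- Biostrings::reverseComplement(dna)
      as.character(Biostrings::translate(dna, no.init.codon = TRUE))
    }
    ref_aa <- strsplit(get_cds(seqchr), "")[[1]]
    alt_aa <- strsplit(get_cds(mut), "")[[1]]
    diff <- which(ref_aa != alt_aa)
    if (length(diff) == 0) return("synonymous")
    if (alt_aa[diff] == "*") return("nonsense")
    if (ref_aa[diff] == "*") return("readthrough")
    return("missense")
  }
  if (pos %in% splice_set) return("splice_site")
  if (pos %in% exon_set) {
    # transcript coordinate by counting exonic bases 5' of pos on the strand
    before <- if (gene$strand == "+") {
      sum(exon_set < pos)
    } else {
      sum(exon_set > pos)
    }
    cds_tx <- if (gene$strand == "+") {
      sum(exon_set < min(cds_set))
    } else {
      sum(exon_set > max(cds_set))
    }
    if (length(cds_set) == 0) return("utr5")
    return(if (before < cds_tx) "utr5" else "utr3")
  }
  "intron"
}

# Jaccard index of two half-open intervals on the same chromosome.
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  inter / union
}
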
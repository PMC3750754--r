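# Hand-built fixtures shared across test files.

# A 100 bp chromosome carrying one two-exon gene with a single-codon CDS:
#   exon1 [10,25), intron [25,35), exon2 [35,50)
#   CDS [20,23) = "GGA" (Gly); utr5 [10,20); utr3 [23,25)+[35,50)
#   donor GT at [25,27), acceptor AG at [33,35)
mini_genome <- function(strand = "+") {
  seqvec <- rep("A", 100)
  seqvec[21:23] <- c("G", "G", "A")         # CDS codon (1-based index)
  seqvec[26:27] <- c("G", "T")              # donor
  seqvec[34:35] <- c("A", "G")              # acceptor
  genes <- tibble::tibble(
    gene_id = "gX", chrom = "chrT", strand = "+",
    exons = list(tibble::tibble(start = c(10L, 35L), end = c(25L, 50L))),
    cds = list(tibble::tibble(start = 20L, end = 23L))
  )
  g <- rohscan::genome_bundle(c(chrT = paste(seqvec, collapse = "")),
                              genes = genes)
  if (strand == "-") mirror_genome(g) else g
}

# Reflect a genome bundle: reverse-complement every chromosome and mirror all
# gene coordinates, flipping strands. A SNP at pos p with alleles (r, a) maps
# to L-1-p with complemented alleles and must classify identically.
mirror_genome <- function(bundle) {
  seqs <- vapply(bundle$sequences, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  genes <- bundle$genes
  for (i in seq_len(nrow(genes))) {
    L <- bundle$lengths[[genes$chrom[i]]]
    flip <- function(iv) {
      tibble::tibble(start = L - iv$end, end = L - iv$start) |>
        dplyr::arrange(start)
    }
    genes$exons[[i]] <- flip(genes$exons[[i]])
    genes$cds[[i]] <- flip(genes$cds[[i]])
    genes$strand[i] <- if (genes$strand[i] == "+") "-" else "+"
  }
  rohscan::genome_bundle(seqs, genes = genes)
}

mirror_snps <- function(variants, lengths) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  variants |>
    dplyr::mutate(pos = unname(lengths[chrom]) - 1L - pos,
                  ref = unname(comp[ref]), alt = unname(comp[alt]))
}

# The benchmark tract geometry: two 4-bin tracts at the ends of a 10-bin
# chromosome, per breed (see the methods vignette for the rationale).
edge_tracts <- function(breeds = c("HW", "BA", "HO"), bin = 400000L,
                        chrom = "chr1") {
  tibble::tibble(
    breed = rep(breeds, each = 2),
    chrom = chrom,
    start = rep(c(0L, 6L * bin), length(breeds)),
    end = rep(c(4L * bin, 10L * bin), length(breeds))
  )
}

# n intervals on one chromosome totalling total_bp (first interval takes the
# remainder), for reproducing printed count/length arithmetic.
make_intervals <- function(n, total_bp, breed = "X", bin = 400000L) {
  rest <- total_bp - (n - 1) * bin
  stopifnot(rest > 0)
  starts <- seq(0, by = 2e7, length.out = n)
  tibble::tibble(
    chrom = "chr1",
    start = as.numeric(starts),
    end = as.numeric(starts + c(rest, rep(bin, n - 1))),
    breed = breed
  )
}

# Minimal single-sample variants tibble builder.
make_variants <- function(chrom, pos, ref, alt, gt1, gt2, breed = "HW",
                          sample_id = "HW_01", depth = 30L, score = NA_real_,
                          known = FALSE) {
  n <- length(pos)
  tibble::tibble(
    breed = rep_len(breed, n), sample_id = rep_len(sample_id, n),
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    gt1 = as.integer(rep_len(gt1, n)), gt2 = as.integer(rep_len(gt2, n)),
    depth = rep_len(as.integer(depth), n),
    ad = lapply(seq_len(n), function(i) c(15L, 15L)),
    score = rep_len(score, n), known = rep_len(known, n),
    is_indel = nchar(rep_len(ref, n)) != nchar(rep_len(alt, n))
  )
}
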
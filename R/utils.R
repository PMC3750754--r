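# Shared low-level helpers. All genomic coordinates inside the package are
# 0-based half-open; 1-based fully-closed appears only at VCF/GFF3/array-TSV
# boundaries.

#' Reverse-complement a nucleotide string
#'
#' Plain-character convenience wrapper used on short alleles and codons.
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of the same length.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# Standard nuclear genetic code (NCBI table 1), taken from Biostrings.
translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[toupper(codons)])
}

#' Normalize a variant's allele representation
#'
#' Trims bases shared by REF and all ALTs: first common trailing bases, then
#' common leading bases beyond the single anchor base indels require. `pos`
#' advances by one for every leading base removed.
#'
#' @param pos 0-based position of the first REF base.
#' @param ref REF allele string.
#' @param alts Character vector of ALT alleles.
#' @return List with elements `pos`, `ref`, `alts`.
#' @keywords internal
#' @noRd
normalize_alleles <- function(pos, ref, alts) {
  alleles <- c(ref, alts)
  # trim shared trailing bases
  repeat {
    lens <- nchar(alleles)
    if (any(lens <= 1L)) break
    lasts <- substr(alleles, lens, lens)
    if (length(unique(lasts)) != 1L) break
    alleles <- substr(alleles, 1L, lens - 1L)
  }
  # trim shared leading bases, keeping one anchor base where needed
  repeat {
    lens <- nchar(alleles)
    if (any(lens <= 1L)) break
    firsts <- substr(alleles, 1L, 1L)
    if (length(unique(firsts)) != 1L) break
    alleles <- substr(alleles, 2L, lens)
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = alleles[1L], alts = alleles[-1L])
}

#' Convert an interval tibble to GRanges
#'
#' @param df Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return A `GenomicRanges::GRanges` (1-based closed, as the class requires).
#' @keywords internal
#' @noRd
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Zygosity of a genotype from its allele indices
#'
#' Homozygous iff both allele indices are present and equal; multiallelic
#' genotypes are judged from the index pair alone.
#'
#' @keywords internal
#' @noRd
is_hom <- function(gt1, gt2) !is.na(gt1) & !is.na(gt2) & gt1 == gt2

is_variant_gt <- function(gt1, gt2) {
  !is.na(gt1) & !is.na(gt2) & (gt1 > 0L | gt2 > 0L)
}
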
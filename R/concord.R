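# Chip-versus-sequencing genotype concordance: the 3x3+missing confusion
# table and the derived metrics (overall concordance, non-reference
# sensitivity, non-reference discrepancy, hom/het discordance).

GT_STATES <- c("AA", "AB", "BB", "NN")

#' Build a genotype concordance table
#'
#' Matches array sites to sequencing genotypes on (chromosome, position) with
#' allele reconciliation (array A = reference allele, B = alternate allele);
#' sites whose alleles disagree between platforms are excluded and reported.
#' Every shared site contributes to exactly one cell of the 3x3+missing
#' grid (rows: array call, columns: sequencing call). Array sites absent from
#' the sequencing callset count as sequencing-missing, or as homozygous
#' reference when `assume_hom_ref = TRUE`.
#'
#' @param array Array matrix tibble.
#' @param variants Sequencing variants tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `gt1`, `gt2`), one sample.
#' @param sample Array column to compare (default: the single sample column).
#' @param assume_hom_ref Treat array sites missing from the callset as
#'   sequencing AA instead of missing (default `FALSE`).
#' @return Object of class `concordance_table`: a list with `counts`
#'   (4x4 integer matrix), `n_shared`, and `excluded` (allele-mismatch
#'   sites).
#' @export
concordance_table <- function(array, variants, sample = NULL,
                              assume_hom_ref = FALSE) {
  meta <- c("site_id", "chrom", "pos", "ref", "alt")
  stopifnot_cols(array, meta, "array matrix")
  sample_cols <- setdiff(names(array), meta)
  sample <- sample %||% sample_cols[1]
  if (!sample %in% sample_cols) {
    abort(sprintf("sample '%s' not found in array matrix", sample))
  }
  seqs <- variants |>
    distinct(chrom, pos, .keep_all = TRUE) |>
    mutate(seq_call = dplyr::case_when(
      is.na(gt1) | is.na(gt2) ~ "NN",
      gt1 == 0L & gt2 == 0L ~ "AA",
      gt1 != gt2 ~ "AB",
      TRUE ~ "BB"
    )) |>
    select(chrom, pos, seq_ref = ref, seq_alt = alt, seq_call)
  joined <- array |>
    select(all_of(meta), array_call = all_of(sample)) |>
    left_join(seqs, by = c("chrom", "pos"))
  mismatch <- !is.na(joined$seq_ref) &
    (joined$ref != joined$seq_ref | joined$alt != joined$seq_alt)
  excluded <- joined[mismatch, c("chrom", "pos", "ref", "alt",
                                 "seq_ref", "seq_alt")]
  joined <- joined[!mismatch, , drop = FALSE]
  joined$seq_call[is.na(joined$seq_call)] <-
    if (assume_hom_ref) "AA" else "NN"
  counts <- table(factor(joined$array_call, levels = GT_STATES),
                  factor(joined$seq_call, levels = GT_STATES))
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(array = GT_STATES, seq = GT_STATES))
  new_concordance_table(counts, excluded = excluded)
}

#' Build a concordance table from printed counts
#'
#' For reproducing worked arithmetic from published confusion counts.
#'
#' @param counts 3x3 or 4x4 matrix of counts; rows are array (truth-role)
#'   calls AA/AB/BB(/NN), columns sequencing calls.
#' @return A `concordance_table`.
#' @export
concordance_table_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (all(dim(counts) == c(3, 3))) {
    full <- matrix(0L, 4, 4, dimnames = list(array = GT_STATES,
                                             seq = GT_STATES))
    full[1:3, 1:3] <- as.integer(counts)
    counts <- full
  } else if (all(dim(counts) == c(4, 4))) {
    dimnames(counts) <- list(array = GT_STATES, seq = GT_STATES)
    storage.mode(counts) <- "integer"
  } else {
    abort("counts must be a 3x3 or 4x4 matrix")
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  new_concordance_table(counts)
}

new_concordance_table <- function(counts, excluded = NULL) {
  structure(
    list(counts = counts,
         n_shared = sum(counts),
         excluded = excluded %||% tibble(chrom = character(0),
                                         pos = integer(0))),
    class = "concordance_table"
  )
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("<concordance_table> %d shared sites (%d excluded for allele mismatch)\n",
              x$n_shared, nrow(x$excluded)))
  print(x$counts)
  invisible(x)
}

# co-called submatrix (both platforms called)
called_counts <- function(t) t$counts[1:3, 1:3]

#' Overall genotype concordance
#'
#' Fraction of co-called sites (both platforms gave an AA/AB/BB call) where
#' the two calls agree.
#'
#' @param t A `concordance_table`.
#' @return Ratio in \[0,1\]; `NA` when no sites are co-called.
#' @export
overall_concordance <- function(t) {
  cc <- called_counts(t)
  denom <- sum(cc)
  if (denom == 0) return(NA_real_)
  sum(diag(cc)) / denom
}

#' Non-reference sensitivity and discrepancy
#'
#' `non_ref_sensitivity()`: among co-called sites where the truth-role call is
#' a variant (AB or BB), the fraction where the evaluated call is also a
#' variant. `non_ref_discrepancy()`: discordant co-called genotypes divided
#' by co-called genotypes excluding concordant homozygous-reference cells.
#' The array is the truth role by default; `truth = "seq"` swaps the roles.
#' A zero denominator yields `NA` (signaled, never silently 0).
#'
#' @param t A `concordance_table`.
#' @param truth Which platform plays the truth role, `"array"` or `"seq"`.
#' @return Ratio in \[0,1\] or `NA`.
#' @export
non_ref_sensitivity <- function(t, truth = c("array", "seq")) {
  truth <- match.arg(truth)
  cc <- called_counts(t)
  if (truth == "seq") cc <- t(cc)
  denom <- sum(cc[c("AB", "BB"), ])
  if (denom == 0) return(NA_real_)
  sum(cc[c("AB", "BB"), c("AB", "BB")]) / denom
}

#' @rdname non_ref_sensitivity
#' @export
non_ref_discrepancy <- function(t) {
  cc <- called_counts(t)
  denom <- sum(cc) - cc["AA", "AA"]
  if (denom == 0) return(NA_real_)
  (sum(cc) - sum(diag(cc))) / denom
}

#' Zygosity-conditional discordance
#'
#' `hom_discordance()`: among co-called sites where the array call is
#' homozygous (AA or BB), the fraction called heterozygous by sequencing.
#' `het_discordance()`: among co-called array-heterozygous sites, the
#' fraction called homozygous by sequencing.
#'
#' @param t A `concordance_table`.
#' @return Ratio in \[0,1\] or `NA` on a zero denominator.
#' @export
hom_discordance <- function(t) {
  cc <- called_counts(t)
  denom <- sum(cc[c("AA", "BB"), ])
  if (denom == 0) return(NA_real_)
  sum(cc[c("AA", "BB"), "AB"]) / denom
}

#' @rdname hom_discordance
#' @export
het_discordance <- function(t) {
  cc <- called_counts(t)
  denom <- sum(cc["AB", ])
  if (denom == 0) return(NA_real_)
  sum(cc["AB", c("AA", "BB")]) / denom
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a concordance table into long counts
#'
#' @param x A `concordance_table`.
#' @param ... Unused.
#' @return Tibble with `array_call`, `seq_call`, `n`.
#' @method tidy concordance_table
#' @export
tidy.concordance_table <- function(x, ...) {
  expand.grid(array_call = GT_STATES, seq_call = GT_STATES,
              stringsAsFactors = FALSE) |>
    as_tibble() |>
    mutate(n = as.integer(x$counts[cbind(array_call, seq_call)]))
}

#' One-row summary of concordance metrics
#'
#' @param x A `concordance_table`.
#' @param ... Unused.
#' @return Tibble with `n_shared`, `n_co_called`, `overall_concordance`,
#'   `non_ref_sensitivity`, `non_ref_discrepancy`, `hom_discordance`,
#'   `het_discordance`.
#' @method glance concordance_table
#' @export
glance.concordance_table <- function(x, ...) {
  tibble(
    n_shared = x$n_shared,
    n_co_called = sum(called_counts(x)),
    overall_concordance = overall_concordance(x),
    non_ref_sensitivity = non_ref_sensitivity(x),
    non_ref_discrepancy = non_ref_discrepancy(x),
    hom_discordance = hom_discordance(x),
    het_discordance = het_discordance(x)
  )
}
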
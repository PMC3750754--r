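# Study-style summary tables: ROH summaries per breed and set, variant
# zygosity/novelty summaries, and depth-track coverage statistics.

# Round-half-even at k decimals (R's round), plus the truncation variant that
# matches how some published tables were evidently produced.
trunc_dp <- function(x, k) trunc(x * 10^k) / 10^k

#' Summarize ROH sets per breed
#'
#' One row per breed for the full ROH set and, when a `specific` column is
#' present (see [specific_rohs()]), one for the specific-ROH (sROH) set.
#' Lengths are reported in Mb: totals rounded to 1 decimal, means to 2
#' decimals (round-half-even), with a truncated mean alongside since
#' truncation at 2 decimals is how such tables are sometimes printed. Gene,
#' trait-gene and NS/SS/I counts are deduplicated by gene and by variant.
#'
#' @param rohs ROH tibble (`chrom`, `start`, `end`, `breed`, optionally
#'   `platform` and `specific`).
#' @param genes Optional gene table for gene counts.
#' @param trait_map Optional trait map (`gene_id`, `trait`) for
#'   trait-associated gene counts.
#' @param nssi Optional [build_nssi()] table for NS/SS/I counts inside ROHs.
#' @return Tibble: `breed`, `set` (ROH/sROH), `n_rohs`, `total_len_mb`,
#'   `mean_len_mb`, `mean_len_mb_trunc`, `gene_count`, `trait_gene_count`,
#'   `nssi_count`, `novel_nssi_count`, and for sROH rows `n_fragments` (the
#'   subtracted-fragment count, which can exceed `n_rohs`).
#' @export
summarize_rohs <- function(rohs, genes = NULL, trait_map = NULL, nssi = NULL) {
  stopifnot_cols(rohs, c("chrom", "start", "end", "breed"), "rohs")
  sets <- list(ROH = rohs)
  if ("specific" %in% names(rohs)) {
    sets$sROH <- rohs |> filter(specific)
  }
  fragments <- if ("specific" %in% names(rohs) && "platform" %in% names(rohs)) {
    subtract_rohs(rohs)
  } else NULL

  rows <- list()
  for (set_name in names(sets)) {
    rr <- sets[[set_name]]
    for (b in unique(rohs$breed)) {
      rb <- rr |> filter(breed == b)
      n <- nrow(rb)
      total <- sum(rb$end - rb$start)
      gene_ids <- character(0)
      if (!is.null(genes) && n > 0) {
        gene_ids <- unique(genes_in_rohs(rb, genes)$gene_id)
      }
      trait_genes <- 0L
      if (!is.null(trait_map) && length(gene_ids) > 0) {
        trait_genes <- length(intersect(gene_ids, unique(trait_map$gene_id)))
      }
      nssi_n <- 0L; nssi_novel <- 0L
      if (!is.null(nssi) && n > 0 && nrow(nssi) > 0) {
        inside <- nssi_in_intervals(nssi, rb)
        nssi_n <- nrow(inside)
        nssi_novel <- sum(inside$novel)
      }
      rows[[length(rows) + 1L]] <- tibble(
        breed = b, set = set_name, n_rohs = n,
        total_len_mb = round(total / 1e6, 1),
        mean_len_mb = if (n == 0) NA_real_ else round(total / n / 1e6, 2),
        mean_len_mb_trunc = if (n == 0) NA_real_ else trunc_dp(total / n / 1e6, 2),
        gene_count = length(gene_ids),
        trait_gene_count = trait_genes,
        nssi_count = nssi_n,
        novel_nssi_count = nssi_novel,
        n_fragments = if (set_name == "sROH" && !is.null(fragments)) {
          sum(fragments$breed == b)
        } else NA_integer_
      )
    }
  }
  bind_rows(rows)
}

# distinct NS/SS/I variants whose position falls in any of the intervals
nssi_in_intervals <- function(nssi, intervals) {
  v <- nssi |> distinct(chrom, pos, ref, alt, .keep_all = TRUE)
  keep <- rep(FALSE, nrow(v))
  for (j in seq_len(nrow(intervals))) {
    keep <- keep | (v$chrom == intervals$chrom[j] &
                      v$pos >= intervals$start[j] &
                      v$pos < intervals$end[j])
  }
  v[keep, , drop = FALSE]
}

#' Zygosity, novelty and indel summary of a callset
#'
#' Counts variant genotypes (at least one non-reference allele) per breed:
#' heterozygous/homozygous split with percentages at 1 decimal, the het:hom
#' ratio at 2 decimals, novel fraction, and the insertion/deletion split of
#' indels.
#'
#' @param variants Variants tibble (`breed`, `gt1`, `gt2`, `ref`, `alt`, and
#'   optionally `known`, `is_indel`).
#' @param known_sites Optional catalogue overriding the `known` column.
#' @return Tibble, one row per breed.
#' @export
summarize_variants <- function(variants, known_sites = NULL) {
  stopifnot_cols(variants, c("breed", "chrom", "pos", "ref", "alt",
                             "gt1", "gt2"), "variants")
  v <- variants |> filter(is_variant_gt(gt1, gt2))
  if (!is.null(known_sites)) {
    kn <- known_sites |> mutate(.known = TRUE)
    v <- v |>
      left_join(kn |> select(chrom, pos, ref, alt, .known),
                by = c("chrom", "pos", "ref", "alt")) |>
      mutate(known = .data$.known %in% TRUE) |>
      select(-".known")
  } else if (!"known" %in% names(v)) {
    v <- v |> mutate(known = FALSE)
  }
  if (!"is_indel" %in% names(v)) {
    v <- v |> mutate(is_indel = nchar(ref) != nchar(alt))
  }
  v |>
    mutate(het = gt1 != gt2,
           is_ins = is_indel & nchar(alt) > nchar(ref),
           is_del = is_indel & nchar(alt) < nchar(ref)) |>
    group_by(breed) |>
    summarise(
      n_variants = n(),
      n_snps = sum(!is_indel),
      n_indels = sum(is_indel),
      n_ins = sum(is_ins),
      n_del = sum(is_del),
      n_het = sum(het),
      n_hom = sum(!het),
      het_pct = round(100 * sum(het) / n(), 1),
      hom_pct = round(100 * sum(!het) / n(), 1),
      het_hom_ratio = round(sum(het) / sum(!het), 2),
      n_novel = sum(!known),
      novel_pct = round(100 * sum(!known) / n(), 1),
      .groups = "drop"
    )
}

#' Zygosity summary from printed counts
#'
#' The same percentages and het:hom ratio as [summarize_variants()], computed
#' from already-tabulated homozygote/heterozygote counts.
#'
#' @param n_hom,n_het Non-negative counts.
#' @return Tibble with `n_variants`, `het_pct`, `hom_pct`, `het_hom_ratio`.
#' @export
zygosity_summary <- function(n_hom, n_het) {
  stopifnot(n_hom >= 0, n_het >= 0, n_hom + n_het > 0)
  n <- n_hom + n_het
  tibble(
    n_variants = n,
    het_pct = round(100 * n_het / n, 1),
    hom_pct = round(100 * n_hom / n, 1),
    het_hom_ratio = if (n_hom == 0) NA_real_ else round(n_het / n_hom, 2)
  )
}

#' Coverage statistics from a depth track
#'
#' @param track Run-length depth track: tibble with `chrom`, `start`, `end`
#'   (0-based half-open), `depth`.
#' @param min_depth Minimum depth for a position to count as covered
#'   (default 1).
#' @return One-row tibble: `total_bp`, `mean_depth` (total bases over total
#'   length), `coverage_pct` (positions at or above `min_depth`, percent at
#'   1 decimal).
#' @export
coverage_stats <- function(track, min_depth = 1) {
  stopifnot_cols(track, c("chrom", "start", "end", "depth"), "depth track")
  len <- track$end - track$start
  if (any(len <= 0)) abort("depth track intervals must have end > start")
  total <- sum(len)
  tibble(
    total_bp = total,
    mean_depth = sum(track$depth * len) / total,
    coverage_pct = round(100 * sum(len[track$depth >= min_depth]) / total, 1)
  )
}
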
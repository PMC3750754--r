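# Readers and writers for the standard formats the pipeline touches.
# Internal coordinates are 0-based half-open; VCF, GFF3, the array TSV and the
# known-sites TSV are 1-based at the file boundary; BED is 0-based half-open
# as the format demands.

#' Read a reference FASTA into a genome bundle (no genes)
#'
#' @param path FASTA file.
#' @param genes Optional gene table to attach (see [genome_bundle()]).
#' @return A [genome_bundle()].
#' @export
read_fasta <- function(path, genes = empty_gene_table()) {
  ss <- Biostrings::readDNAStringSet(path)
  genome_bundle(setNames(as.character(ss), names(ss)), genes = genes)
}

#' Write a genome bundle's sequences to FASTA
#'
#' @param bundle A [genome_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(bundle, path) {
  ss <- Biostrings::DNAStringSet(bundle$sequences)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# ---- VCF ---------------------------------------------------------------

#' Write a variants tibble as VCF v4.2
#'
#' One row per site; samples become genotype columns with GT:DP:AD. The
#' per-site deleteriousness score and known-catalogue flag are carried in
#' INFO as `SCORE=` and `KNOWN` so a round trip preserves them.
#'
#' @param variants Tibble with columns `sample_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `gt1`, `gt2`, and optionally `depth`, `ad`, `score`,
#'   `known`.
#' @param path Output path (plain text).
#' @param chrom_lengths Optional named lengths for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, chrom_lengths = NULL) {
  stopifnot_cols(variants, c("sample_id", "chrom", "pos", "ref", "alt",
                             "gt1", "gt2"), "variants")
  samples <- unique(variants$sample_id)
  has_dp <- "depth" %in% names(variants)
  has_ad <- "ad" %in% names(variants)
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_ad) "AD"), collapse = ":")

  site <- variants |>
    distinct(chrom, pos, ref, alt, .keep_all = TRUE) |>
    arrange(chrom, pos)
  info <- rep(".", nrow(site))
  if ("score" %in% names(site)) {
    info <- if_else(is.na(site$score), info, sprintf("SCORE=%g", site$score))
  }
  if ("known" %in% names(site)) {
    info <- if_else(site$known %in% TRUE, paste0(info, ";KNOWN"), info)
    info <- sub("^\\.;", "", info)
  }

  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  site_key <- paste(site$chrom, site$pos, site$ref, site$alt)
  gt_cols <- matrix("./.", nrow = nrow(site), ncol = length(samples),
                    dimnames = list(NULL, samples))
  cell <- variants |>
    mutate(
      gt = if_else(is.na(gt1) | is.na(gt2), "./.",
                   paste0(gt1, "/", gt2)),
      field = gt
    )
  if (has_dp) {
    cell$field <- paste0(cell$field, ":",
                         if_else(is.na(cell$depth), ".", as.character(cell$depth)))
  }
  if (has_ad) {
    cell$field <- paste0(cell$field, ":",
                         vapply(cell$ad, function(a) {
                           if (is.null(a) || all(is.na(a))) "." else
                             paste(a, collapse = ",")
                         }, character(1)))
  }
  gt_cols[cbind(match(key, site_key), match(variants$sample_id, samples))] <-
    cell$field

  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Deleteriousness score in [0,1]\">",
    "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Site present in the known-variant catalogue\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (has_ad) "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(site$chrom, site$pos + 1L, ".", site$ref, site$alt, ".",
                "PASS", info, fmt,
                apply(gt_cols, 1L, paste, collapse = "\t"),
                sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a variants tibble
#'
#' Parses VCF v4.2 via \pkg{vcfR}. Genotypes with missing GT are kept as
#' missing records; alleles are normalized by trimming shared trailing bases
#' and shared leading bases beyond the anchor base. Multiallelic rows are
#' preserved as one record with a comma-separated `alt`.
#'
#' @param path VCF file (plain text or gzip).
#' @return Tibble with one row per site x sample: `sample_id`, `chrom`, `pos`
#'   (0-based), `ref`, `alt`, `gt1`, `gt2`, `depth`, `ad` (list column),
#'   `score`, `known`.
#' @export
read_vcf <- function(path) {
  check_vcf_layout(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  pos <- as.integer(fix$POS) - 1L
  ref <- fix$REF
  alt <- fix$ALT
  # allele normalization
  for (i in seq_len(n)) {
    norm <- normalize_alleles(pos[i], ref[i], strsplit(alt[i], ",")[[1]])
    pos[i] <- norm$pos
    ref[i] <- norm$ref
    alt[i] <- paste(norm$alts, collapse = ",")
  }
  info <- fix$INFO %||% rep(".", n)
  score <- suppressWarnings(
    as.numeric(stringr::str_match(info, "SCORE=([0-9eE.+-]+)")[, 2])
  )
  known <- stringr::str_detect(info, "(^|;)KNOWN(;|$)")

  samples <- colnames(v@gt)[-1]
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- if (any(grepl("DP", v@gt[, "FORMAT"]))) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else NULL
  ad <- if (any(grepl("AD", v@gt[, "FORMAT"]))) {
    vcfR::extract.gt(v, element = "AD")
  } else NULL

  out <- lapply(samples, function(s) {
    g <- gt[, s]
    pieces <- stringr::str_split_fixed(g, "[/|]", 2)
    gt1 <- suppressWarnings(as.integer(pieces[, 1]))
    gt2 <- suppressWarnings(as.integer(pieces[, 2]))
    tibble(
      sample_id = s, chrom = fix$CHROM, pos = pos, ref = ref, alt = alt,
      gt1 = gt1, gt2 = gt2,
      depth = if (is.null(dp)) NA_integer_ else as.integer(dp[, s]),
      ad = if (is.null(ad)) {
        rep(list(NULL), n)
      } else {
        unname(lapply(ad[, s], function(a) {
          if (is.na(a)) NULL else as.integer(strsplit(a, ",")[[1]])
        }))
      },
      score = score, known = known
    )
  })
  bind_rows(out) |>
    mutate(is_indel = nchar(ref) > 1 |
             vapply(strsplit(alt, ","), function(a) any(nchar(a) > 1),
                    logical(1))) |>
    arrange(sample_id, chrom, pos)
}

# Light structural validation so malformed rows error with a line number.
check_vcf_layout <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1) abort("not a VCF: missing #CHROM header line")
  n_fields <- length(strsplit(lines[hdr], "\t")[[1]])
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body_idx) {
    k <- length(strsplit(lines[i], "\t")[[1]])
    if (k != n_fields) {
      abort(sprintf("malformed VCF row at line %d: %d fields, expected %d",
                    i, k, n_fields))
    }
  }
  invisible(TRUE)
}

# ---- Array matrix TSV --------------------------------------------------

#' Write an array genotype matrix to TSV
#'
#' Columns: `site_id`, `chrom`, `pos` (1-based in the file), `ref`, `alt`,
#' then one AA/AB/BB/NN column per individual.
#'
#' @param matrix Array matrix tibble (0-based `pos` internally).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_array <- function(matrix, path) {
  stopifnot_cols(matrix, c("site_id", "chrom", "pos", "ref", "alt"),
                 "array matrix")
  out <- matrix |> mutate(pos = pos + 1L)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an array genotype matrix from TSV
#'
#' Validates that calls are in AA/AB/BB/NN and that every site has a distinct
#' (chromosome, position).
#'
#' @param path TSV file written by [write_array()] or of the same layout.
#' @return Array matrix tibble with 0-based `pos`.
#' @export
read_array <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(m, c("site_id", "chrom", "pos", "ref", "alt"), "array matrix")
  m <- m |> mutate(pos = as.integer(pos) - 1L)
  sample_cols <- setdiff(names(m), c("site_id", "chrom", "pos", "ref", "alt"))
  if (length(sample_cols) == 0) abort("array matrix has no sample columns")
  for (sc in sample_cols) {
    bad <- !m[[sc]] %in% c("AA", "AB", "BB", "NN")
    if (any(bad)) {
      abort(sprintf("array column %s has invalid call '%s' at row %d",
                    sc, m[[sc]][bad][1], which(bad)[1]))
    }
  }
  if (anyDuplicated(paste(m$chrom, m$pos))) {
    abort("array matrix has duplicated (chromosome, position) sites")
  }
  m
}

# ---- Gene models (GFF3) ------------------------------------------------

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based closed coordinates, as
#' GFF3 requires) with `Parent` links; one transcript per gene.
#'
#' @param genes Gene table (see [genome_bundle()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    cds <- g$cds[[1]]
    span <- c(min(ex$start), max(ex$end))
    tx_id <- paste0(g$gene_id, ".t1")
    lines <- c(
      lines,
      sprintf("%s\trohscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, span[1] + 1L, span[2], g$strand, g$gene_id),
      sprintf("%s\trohscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, span[1] + 1L, span[2], g$strand, tx_id, g$gene_id),
      sprintf("%s\trohscan\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$chrom, ex$start + 1L, ex$end, g$strand, tx_id),
      if (nrow(cds) > 0) {
        sprintf("%s\trohscan\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                g$chrom, cds$start + 1L, cds$end, g$strand, tx_id)
      }
    )
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads via \pkg{rtracklayer} and converts 1-based closed coordinates to the
#' internal 0-based half-open convention. Expects one transcript per gene
#' (mRNA features with exon/CDS children linked by `Parent`).
#'
#' @param path GFF3 file.
#' @param chrom_lengths Optional named chromosome lengths; coordinates
#'   outside a declared length raise a validation error.
#' @return Gene table (see [genome_bundle()]).
#' @export
read_genes <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID %||% NA_character_),
    parent = vapply(as.list(gr$Parent %||% rep(list(character(0)), length(gr))),
                    function(p) if (length(p) == 0) NA_character_ else p[1],
                    character(1))
  )
  mrna <- df |> filter(type == "mRNA")
  rows <- lapply(seq_len(nrow(mrna)), function(i) {
    tx <- mrna[i, ]
    kids <- df |> filter(parent == tx$id)
    ex <- kids |> filter(type == "exon") |> arrange(start)
    cds <- kids |> filter(type == "CDS") |> arrange(start)
    tibble(
      gene_id = tx$parent, chrom = tx$chrom, strand = tx$strand,
      exons = list(tibble(start = ex$start, end = ex$end)),
      cds = list(tibble(start = cds$start, end = cds$end))
    )
  })
  genes <- bind_rows(rows)
  if (!is.null(chrom_lengths)) {
    spans <- gene_spans(genes)
    bad <- spans$end > chrom_lengths[spans$chrom] | spans$start < 0
    if (any(bad)) {
      abort(sprintf("gene %s extends beyond declared chromosome length",
                    spans$gene_id[bad][1]))
    }
  }
  for (i in seq_len(nrow(genes))) validate_gene_model(genes[i, ])
  genes
}

# ---- BED ---------------------------------------------------------------

#' Write intervals as BED6
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot_cols(intervals, c("chrom", "start", "end"), "intervals")
  out <- tibble(
    chrom = intervals$chrom,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = intervals$name %||% ".",
    score = intervals$score %||% 0,
    strand = intervals$strand %||% "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval tibble
#'
#' @param path BED3+ file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  m <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  names(m) <- cols[seq_len(ncol(m))]
  m |> mutate(start = as.integer(start), end = as.integer(end))
}

# ---- Known sites, scores, trait map ------------------------------------

#' Read or write a known-variant catalogue
#'
#' TSV with columns `chrom`, `pos` (1-based in the file), `ref`, `alt`.
#'
#' @param path TSV file.
#' @return Tibble with 0-based `pos`.
#' @export
read_known_sites <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(m, c("chrom", "pos", "ref", "alt"), "known sites")
  m |> mutate(pos = as.integer(pos) - 1L)
}

#' @rdname read_known_sites
#' @param sites Tibble with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @export
write_known_sites <- function(sites, path) {
  readr::write_tsv(sites |> mutate(pos = pos + 1L), path)
  invisible(path)
}

#' Read a trait map (gene to trait category)
#'
#' @param path TSV with columns `gene_id`, `trait`.
#' @return Tibble.
#' @export
read_trait_map <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(m, c("gene_id", "trait"), "trait map")
  m
}
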
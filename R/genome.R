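# Toy reference genomes with gene models: the coordinate ground truth that the
# annotator and the simulator share.

#' Construct a genome bundle
#'
#' A genome bundle holds the reference sequences and the representative gene
#' models (one transcript per gene) used for consequence annotation and
#' simulation. Coordinates are 0-based half-open.
#'
#' @param sequences Named character vector or list, chromosome name to
#'   uppercase A/C/G/T sequence.
#' @param genes Tibble of gene models with columns `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `exons`, `cds` (list columns of tibbles with
#'   `start`, `end`). May have zero rows.
#' @return An object of class `genome_bundle` with elements `sequences`,
#'   `lengths`, `genes`.
#' @export
genome_bundle <- function(sequences, genes = empty_gene_table()) {
  sequences <- vapply(sequences, as.character, character(1))
  bundle <- structure(
    list(
      sequences = sequences,
      lengths = setNames(nchar(sequences), names(sequences)),
      genes = as_tibble(genes)
    ),
    class = "genome_bundle"
  )
  validate_genome(bundle)
  bundle
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %d chromosome(s), %s bp total, %d gene model(s)\n",
              length(x$sequences), format(sum(x$lengths), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

empty_gene_table <- function() {
  tibble(gene_id = character(), chrom = character(), strand = character(),
         exons = list(), cds = list())
}

#' Validate a genome bundle against its invariants
#'
#' Checks that sequences contain only A/C/G/T, that every gene lies within its
#' chromosome, that exons are sorted and non-overlapping, that CDS intervals
#' are contained in exons with total length a multiple of 3, and that introns
#' are at least 4 bp wide.
#'
#' @param bundle A `genome_bundle`.
#' @return The bundle, invisibly; errors on violation.
#' @export
validate_genome <- function(bundle) {
  bad <- grepl("[^ACGT]", bundle$sequences)
  if (any(bad)) {
    abort(sprintf("chromosome %s contains non-ACGT characters",
                  names(bundle$sequences)[bad][1]))
  }
  genes <- bundle$genes
  if (nrow(genes) > 0) {
    for (i in seq_len(nrow(genes))) {
      validate_gene_model(genes[i, ], bundle$lengths)
    }
  }
  invisible(bundle)
}

validate_gene_model <- function(gene, chrom_lengths = NULL) {
  id <- gene$gene_id
  ex <- gene$exons[[1]]
  cds <- gene$cds[[1]]
  if (!gene$strand %in% c("+", "-")) {
    abort(sprintf("gene %s: strand must be '+' or '-'", id))
  }
  if (nrow(ex) == 0 || any(ex$end <= ex$start)) {
    abort(sprintf("gene %s: exons must be non-empty intervals", id))
  }
  if (is.unsorted(ex$start, strictly = TRUE) ||
      any(head(ex$end, -1) > tail(ex$start, -1))) {
    abort(sprintf("gene %s: exons must be sorted and non-overlapping", id))
  }
  if (nrow(ex) > 1) {
    introns <- tail(ex$start, -1) - head(ex$end, -1)
    if (any(introns < 4)) {
      abort(sprintf("gene %s: introns must be at least 4 bp", id))
    }
  }
  if (nrow(cds) > 0) {
    in_exon <- vapply(seq_len(nrow(cds)), function(j) {
      any(ex$start <= cds$start[j] & cds$end[j] <= ex$end)
    }, logical(1))
    if (!all(in_exon)) {
      abort(sprintf("gene %s: CDS intervals must be contained in exons", id))
    }
    if (sum(cds$end - cds$start) %% 3 != 0) {
      abort(sprintf("gene %s: total CDS length must be a multiple of 3", id))
    }
  }
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[[gene$chrom]]
    if (is.null(len) || is.na(len)) {
      abort(sprintf("gene %s: chromosome %s not in bundle", id, gene$chrom))
    }
    if (min(ex$start) < 0 || max(ex$end) > len) {
      abort(sprintf("gene %s: lies outside chromosome %s", id, gene$chrom))
    }
  }
  invisible(gene)
}

# Genomic positions of the transcript, in transcript (5'->3') order.
gene_tx_positions <- function(gene) {
  ex <- gene$exons[[1]]
  pos <- unlist(lapply(seq_len(nrow(ex)), function(j) {
    seq.int(ex$start[j], ex$end[j] - 1L)
  }), use.names = FALSE)
  if (gene$strand == "-") pos <- rev(pos)
  pos
}

# Genomic positions of the CDS, in transcript order.
gene_cds_positions <- function(gene) {
  cds <- gene$cds[[1]]
  if (nrow(cds) == 0) return(integer(0))
  cds_set <- unlist(lapply(seq_len(nrow(cds)), function(j) {
    seq.int(cds$start[j], cds$end[j] - 1L)
  }), use.names = FALSE)
  tx <- gene_tx_positions(gene)
  tx[tx %in% cds_set]
}

# Intron intervals (gaps between consecutive exons), genomic order.
gene_introns <- function(gene) {
  ex <- gene$exons[[1]]
  if (nrow(ex) < 2) return(tibble(start = integer(0), end = integer(0)))
  tibble(start = head(ex$end, -1), end = tail(ex$start, -1))
}

# Genomic span of a gene (leftmost exon start to rightmost exon end).
gene_spans <- function(genes) {
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = vapply(genes$exons, function(e) min(e$start), integer(1)),
    end = vapply(genes$exons, function(e) max(e$end), integer(1))
  )
}

# Collapse a sorted vector of 0-based positions into half-open intervals.
positions_to_intervals <- function(pos) {
  if (length(pos) == 0) return(tibble(start = integer(0), end = integer(0)))
  pos <- sort(unique(as.integer(pos)))
  breaks <- which(diff(pos) != 1L)
  starts <- pos[c(1L, breaks + 1L)]
  ends <- pos[c(breaks, length(pos))] + 1L
  tibble(start = starts, end = ends)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a toy reference genome with gene models
#'
#' Builds random chromosomes and plants non-overlapping multi-exon gene models
#' on them. Each gene has 2-4 exons, a coding sequence that starts with ATG,
#' contains no internal stop codon and ends with a stop codon, 5' and 3' UTRs,
#' and canonical GT/AG splice dinucleotides written into the reference at its
#' intron ends (strand-aware). Deterministic for a fixed seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp.
#' @param n_genes Total number of gene models to place (round-robin across
#'   chromosomes). Both strands are represented whenever `n_genes >= 2`.
#' @param seed Integer seed.
#' @return A [genome_bundle()].
#' @examples
#' ref <- generate_reference(n_chrom = 1, chrom_len = 50000, n_genes = 2, seed = 7)
#' ref$genes$strand
#' @export
generate_reference <- function(n_chrom = 1, chrom_len = 4e6, n_genes = 10,
                               seed = 1) {
  stopifnot(n_chrom >= 1, chrom_len >= 1000, n_genes >= 0)
  set.seed(seed)
  chrom_names <- paste0("chr", seq_len(n_chrom))
  seqs <- lapply(chrom_names, function(cn) {
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  })
  names(seqs) <- chrom_names

  genes <- empty_gene_table()
  if (n_genes > 0) {
    strands <- sample(rep_len(c("+", "-"), n_genes))
    chroms <- rep_len(chrom_names, n_genes)
    placed <- lapply(chrom_names, function(cn) tibble(start = integer(), end = integer()))
    names(placed) <- chrom_names
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      cn <- chroms[g]
      model <- plan_gene_model()
      span <- model$span_len
      lo <- 1000L
      hi <- chrom_len - span - 1000L
      if (hi <= lo) {
        abort(sprintf("gene layout impossible: span %d bp does not fit on a %d bp chromosome",
                      span, chrom_len),
              class = "rohscan_layout_error")
      }
      start <- NA_integer_
      occupied <- placed[[cn]]
      for (try in 1:200) {
        cand <- as.integer(sample.int(hi - lo, 1L) + lo)
        clash <- any(occupied$start < cand + span + 500L & cand - 500L < occupied$end)
        if (!clash) { start <- cand; break }
      }
      if (is.na(start)) {
        abort("gene layout impossible: could not place gene without overlap",
              class = "rohscan_layout_error")
      }
      placed[[cn]] <- bind_rows(occupied, tibble(start = start, end = start + span))
      gene <- realize_gene_model(model, sprintf("g%03d", g), cn, strands[g], start)
      seqs[[cn]] <- write_gene_sequence(seqs[[cn]], gene, model)
      rows[[g]] <- gene
    }
    genes <- bind_rows(rows)
  }

  genome_bundle(
    sequences = vapply(seqs, paste, character(1), collapse = ""),
    genes = genes
  )
}

# Draw the internal geometry of one gene model (lengths only, no placement).
plan_gene_model <- function() {
  n_exons <- sample(2:4, 1)
  n_codons <- sample(40:150, 1)          # includes the terminal stop codon
  cds_len <- 3L * n_codons
  utr5 <- sample(30:100, 1)
  utr3 <- sample(30:100, 1)
  tx_len <- utr5 + cds_len + utr3
  # composition of tx_len into n_exons parts, each >= 30 bp
  extra <- tx_len - 30L * n_exons
  cuts <- sort(sample.int(extra + 1L, n_exons - 1L, replace = TRUE) - 1L)
  parts <- diff(c(0L, cuts, extra)) + 30L
  introns <- sample(100:1000, n_exons - 1L, replace = TRUE)
  list(n_exons = n_exons, cds_len = cds_len, utr5 = utr5, utr3 = utr3,
       exon_lens = as.integer(parts), intron_lens = as.integer(introns),
       span_len = as.integer(sum(parts) + sum(introns)),
       n_codons = n_codons)
}

# Turn a planned model into a gene row at a genomic start position.
realize_gene_model <- function(model, gene_id, chrom, strand, start) {
  ex_starts <- start + c(0L, cumsum(head(model$exon_lens, -1) + model$intron_lens))
  exons <- tibble(start = as.integer(ex_starts),
                  end = as.integer(ex_starts + model$exon_lens))
  gene <- tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = list(exons), cds = list(tibble(start = integer(0),
                                                        end = integer(0))))
  tx <- gene_tx_positions(gene[1, ])
  cds_tx <- tx[(model$utr5 + 1L):(model$utr5 + model$cds_len)]
  gene$cds[[1]] <- positions_to_intervals(cds_tx)
  gene
}

# Write the coding sequence and splice dinucleotides into the chromosome
# character vector (0-based positions -> 1-based vector index).
write_gene_sequence <- function(seqvec, gene, model) {
  g <- gene[1, ]
  # coding sequence on the coding strand: ATG, non-stop codons, stop
  all_codons <- names(Biostrings::GENETIC_CODE)
  body <- sample(setdiff(all_codons, c(STOP_CODONS, "ATG")),
                 model$n_codons - 2L, replace = TRUE)
  cds_seq <- strsplit(paste0("ATG", paste(body, collapse = ""),
                             sample(STOP_CODONS, 1)), "")[[1]]
  cds_pos <- gene_cds_positions(g)   # transcript order
  if (g$strand == "+") {
    seqvec[cds_pos + 1L] <- cds_seq
  } else {
    seqvec[cds_pos + 1L] <- complement_base(cds_seq)
  }
  introns <- gene_introns(g)
  if (nrow(introns) > 0) {
    for (j in seq_len(nrow(introns))) {
      a <- introns$start[j]; b <- introns$end[j]
      if (g$strand == "+") {
        seqvec[(a + 1L):(a + 2L)] <- c("G", "T")
        seqvec[(b - 1L):b] <- c("A", "G")
      } else {
        # donor at the right end, acceptor at the left end, on the minus strand
        seqvec[(b - 1L):b] <- c("A", "C")
        seqvec[(a + 1L):(a + 2L)] <- c("C", "T")
      }
    }
  }
  seqvec
}
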
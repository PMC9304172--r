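# Readers and writers for the formats the pipeline touches: FASTA, gene
# models (GFF3 or exon-coordinate TSV), SNP-only VCF extracts, and the
# replicate-structured knockout fitness table. Internal coordinates are
# 0-based half-open only inside helper arithmetic; everything stored on
# objects follows the 1-based inclusive GFF3/VCF convention.

FASTA_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased and RNA `U` is mapped to `T`. Identifiers are
#' taken up to the first whitespace of the header line. Any character
#' outside `A/C/G/T/N/-` is an error naming the offending record, as are
#' duplicated identifiers and empty records. Plain and gzip-compressed
#' files are accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0) stop("empty FASTA record: ", ids[i])
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), FASTA_ALPHABET)
    if (length(bad) > 0) {
      stop("record ", ids[i], " contains characters outside A/C/G/T/N/-: ",
           paste(bad, collapse = ""))
    }
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width for sequence wrapping; `Inf` writes one line per
#'   sequence (the default keeps round-trips byte-simple).
#' @export
write_fasta <- function(seqs, path, width = Inf) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Construct a gene model
#'
#' @param gene_id,chrom,strand Gene identifier, chromosome, `"+"` or `"-"`.
#' @param transcripts Named list; each element a data.frame with `start`,
#'   `end` (1-based inclusive CDS intervals).
#' @return A `gene_model` object; transcript intervals are sorted and
#'   checked for overlap, and each transcript's CDS length must be a
#'   positive multiple of 3.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1,
            !is.null(names(transcripts)))
  transcripts <- lapply(transcripts, function(tr) {
    tr <- tr[order(tr$start), c("start", "end"), drop = FALSE]
    if (any(tr$end < tr$start)) stop("interval with end < start")
    if (nrow(tr) > 1 && any(tr$start[-1] <= tr$end[-nrow(tr)])) {
      stop("overlapping CDS intervals in gene ", gene_id)
    }
    tr
  })
  lens <- vapply(transcripts, function(tr) sum(tr$end - tr$start + 1), 0)
  if (any(lens <= 0) || any(lens %% 3 != 0)) {
    stop("CDS length not a positive multiple of 3 in gene ", gene_id)
  }
  # longest CDS; ties broken by lexicographically smallest transcript id
  ids <- names(transcripts)
  best <- ids[lens == max(lens)]
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts,
                 cds_lengths = lens,
                 longest_cds_id = sort(best)[1]),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d transcript(s), longest CDS %s (%d nt)\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts),
              x$longest_cds_id, x$cds_lengths[[x$longest_cds_id]]))
  invisible(x)
}

#' Read gene models from GFF3 or an exon-coordinate TSV
#'
#' GFF3 input uses `CDS` features, resolving transcript ids through `Parent`
#' and gene ids through the parent mRNA/transcript features. The tabular
#' dialect (BioMart-style) needs columns `gene_id`, `transcript_id`,
#' `chrom`, `strand`, `start`, `end`, one CDS interval per row. Transcripts
#' whose summed CDS length is not a positive multiple of 3 are excluded;
#' genes left with no valid transcript are dropped. Exclusions are recorded
#' in the `"log"` attribute of the result.
#'
#' @param path Path to a `.gff`/`.gff3` (optionally gzipped) or TSV file.
#' @return Named list of `gene_model` objects, with attribute `log`
#'   (character vector of exclusion messages).
#' @export
read_gene_models <- function(path) {
  ext <- tolower(sub("\\.gz$", "", path))
  if (grepl("\\.gff3?$", ext)) {
    df <- as.data.frame(rtracklayer::readGFF(path))
    cds <- df[df$type == "CDS", , drop = FALSE]
    if (nrow(cds) == 0) stop("no CDS features in ", path)
    first_parent <- function(p) vapply(p, function(x) {
      if (length(x) == 0) NA_character_ else as.character(x[[1]])
    }, character(1))
    tr_id <- first_parent(cds$Parent)
    # map transcript -> gene via mRNA/transcript features when present
    tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
    tx_gene <- if (nrow(tx) > 0) {
      stats::setNames(first_parent(tx$Parent), as.character(tx$ID))
    } else {
      character(0)
    }
    gene_id <- ifelse(tr_id %in% names(tx_gene), tx_gene[tr_id], tr_id)
    rows <- data.frame(gene_id = gene_id, transcript_id = tr_id,
                       chrom = as.character(cds$seqid),
                       strand = as.character(cds$strand),
                       start = cds$start, end = cds$end,
                       stringsAsFactors = FALSE)
  } else {
    rows <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
    if (!all(need %in% names(rows))) {
      stop("exon TSV must have columns: ", paste(need, collapse = ", "))
    }
  }

  log <- character(0)
  models <- list()
  for (g in unique(rows$gene_id)) {
    sub <- rows[rows$gene_id == g, , drop = FALSE]
    trs <- split(sub[, c("start", "end")], sub$transcript_id)
    lens <- vapply(trs, function(tr) sum(tr$end - tr$start + 1), 0)
    bad <- lens <= 0 | lens %% 3 != 0
    if (any(bad)) {
      log <- c(log, sprintf(
        "gene %s: transcript %s excluded (CDS length %d not a multiple of 3)",
        g, names(trs)[bad], lens[bad]))
      trs <- trs[!bad]
    }
    if (length(trs) == 0) {
      log <- c(log, sprintf("gene %s excluded: no in-frame transcript", g))
      next
    }
    models[[g]] <- gene_model(g, sub$chrom[1], sub$strand[1], trs)
  }
  attr(models, "log") <- log
  models
}

#' Read biallelic SNPs for a region from a VCF
#'
#' Keeps single-nucleotide biallelic records only; indels and multiallelic
#' records are skipped and counted. One row is emitted per accession whose
#' genotype carries the ALT allele; heterozygous calls are resolved to the
#' ALT allele (reasonable for a highly selfing species) and counted in the
#' log attribute.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param region Optional list with `chrom` and optionally `start`, `end`
#'   (1-based inclusive) restricting the extraction.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `accession_id`, with attribute `log` (named counts: `indel`,
#'   `multiallelic`, `het_resolved_alt`).
#' @export
read_vcf_snps <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(region)) {
    contigs <- grep("^##contig", v@meta, value = TRUE)
    if (length(contigs) > 0 &&
        !any(grepl(paste0("ID=", region$chrom, "\\b"), contigs) |
             grepl(paste0("ID=", region$chrom, ","), contigs) |
             grepl(paste0("ID=", region$chrom, ">"), contigs))) {
      stop("contig ", region$chrom, " not present in VCF header")
    }
  }
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  chrom <- fix[, "CHROM"]

  multi <- grepl(",", alt)
  indel <- !multi & (nchar(ref) != 1 | nchar(alt) != 1)
  snp <- !multi & !indel
  in_region <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    in_region <- chrom == region$chrom
    if (!is.null(region$start)) in_region <- in_region & pos >= region$start
    if (!is.null(region$end)) in_region <- in_region & pos <= region$end
  }
  counts <- c(indel = sum(indel & in_region),
              multiallelic = sum(multi & in_region),
              het_resolved_alt = 0L)

  keep <- which(snp & in_region)
  out <- data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    accession_id = character(0), stringsAsFactors = FALSE)
  if (length(keep) > 0 && ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
    carries <- matrix(grepl("1", gt), nrow = nrow(gt),
                      dimnames = dimnames(gt))
    het <- matrix(grepl("0", gt) & grepl("1", gt), nrow = nrow(gt))
    counts["het_resolved_alt"] <- sum(het, na.rm = TRUE)
    idx <- which(carries, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      out <- data.frame(
        chrom = chrom[keep][idx[, 1]],
        pos = pos[keep][idx[, 1]],
        ref = ref[keep][idx[, 1]],
        alt = alt[keep][idx[, 1]],
        accession_id = colnames(gt)[idx[, 2]],
        stringsAsFactors = FALSE)
      out <- out[order(out$accession_id, out$pos), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "log") <- counts
  out
}

# genomic position -> 1-based offset along the mRNA-sense CDS, or NA when
# the position is outside every interval. `intervals` sorted by start.
cds_offset <- function(pos, intervals, strand) {
  lens <- intervals$end - intervals$start + 1
  hit <- which(pos >= intervals$start & pos <= intervals$end)
  if (length(hit) == 0) return(NA_integer_)
  hit <- hit[1]
  if (strand == "+") {
    before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0
    as.integer(before + (pos - intervals$start[hit] + 1))
  } else {
    n <- nrow(intervals)
    after <- if (hit < n) sum(lens[seq(hit + 1, n)]) else 0
    as.integer(after + (intervals$end[hit] - pos + 1))
  }
}

#' Substitute an accession's SNP alleles into a reference CDS
#'
#' The reference CDS is stored 5'->3' in mRNA sense; for minus-strand genes
#' the complemented allele is substituted at the mapped offset. SNPs falling
#' outside the transcript's CDS intervals are ignored. A SNP whose REF
#' allele disagrees with the reference CDS at its mapped offset is an error.
#'
#' @param reference_cds mRNA-sense CDS string of the chosen transcript.
#' @param snps data.frame with `pos`, `ref`, `alt` (one accession's SNPs on
#'   this gene's chromosome).
#' @param model A `gene_model`.
#' @param transcript_id Transcript whose coordinates to use; defaults to the
#'   model's longest CDS.
#' @return The accession's CDS string (same length as `reference_cds`).
#' @export
build_accession_haplotype <- function(reference_cds, snps, model,
                                      transcript_id = model$longest_cds_id) {
  intervals <- model$transcripts[[transcript_id]]
  if (is.null(intervals)) stop("no transcript ", transcript_id)
  if (nchar(reference_cds) != sum(intervals$end - intervals$start + 1)) {
    stop("reference CDS length does not match transcript ", transcript_id)
  }
  out <- strsplit(reference_cds, "")[[1]]
  if (nrow(snps) > 0) {
    for (i in seq_len(nrow(snps))) {
      off <- cds_offset(snps$pos[i], intervals, model$strand)
      if (is.na(off)) next
      ref_allele <- if (model$strand == "+") snps$ref[i] else
        complement_base(snps$ref[i])
      alt_allele <- if (model$strand == "+") snps$alt[i] else
        complement_base(snps$alt[i])
      if (out[off] != ref_allele) {
        stop("SNP REF allele mismatch at genomic position ", snps$pos[i],
             " (CDS offset ", off, "): CDS has ", out[off],
             ", VCF REF maps to ", ref_allele)
      }
      out[off] <- alt_allele
    }
  }
  paste(out, collapse = "")
}

#' Read a knockout fitness table
#'
#' Tab-separated with header `line_id`, `gene_id`, `replicate_id`,
#' `chamber_id`, `ko_fruit_count`, `wt_fruit_count`, `area_ratio`. Fruit
#' counts must be non-negative integers; a blank `area_ratio` is kept as
#' missing (`NA`), which is distinct from 0.
#'
#' @param path Path to the TSV.
#' @return data.frame of class `fitness_table`.
#' @export
read_fitness_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("line_id", "gene_id", "replicate_id", "chamber_id",
            "ko_fruit_count", "wt_fruit_count", "area_ratio")
  if (!all(need %in% names(df))) {
    stop("fitness table must have columns: ", paste(need, collapse = ", "))
  }
  for (col in c("ko_fruit_count", "wt_fruit_count")) {
    x <- df[[col]]
    if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
      stop(col, " must be non-negative integers")
    }
    df[[col]] <- as.integer(x)
  }
  df$area_ratio <- as.numeric(df$area_ratio)
  if (any(!is.na(df$area_ratio) & df$area_ratio < 0)) {
    stop("area_ratio must be non-negative")
  }
  class(df) <- c("fitness_table", "data.frame")
  df
}
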
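# Readers and writers for the toolkit's external formats: FASTA genomes,
# gene annotation (GFF3 or a simple TSV dialect), SNP tables (VCF subset or
# TSV), and the tab-separated marker database.

#' Read a genome FASTA file
#'
#' Parses a multi-record FASTA into a named character vector of upper-case
#' sequences, preserving file order. Characters outside the IUPAC nucleotide
#' alphabet are rejected with the record and offset of the first offender.
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences; one element per
#'   record.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) abort("duplicate scaffold ids in FASTA")
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    bad <- regexpr(paste0("[^", paste(IUPAC_LETTERS, collapse = ""), "]"),
                   seqs[[i]])
    if (bad > 0) {
      abort(sprintf(
        "illegal character '%s' in record '%s' at offset %d",
        substr(seqs[[i]], bad, bad), ids[[i]], as.integer(bad)
      ))
    }
  }
  setNames(seqs, ids)
}

#' Write a genome FASTA file
#'
#' @param genome named character vector (or DNAStringSet) of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene annotation
#'
#' Reads gene models with exon structure from GFF3 (`gene`/`mRNA`/`exon`
#' features) or from a simple TSV dialect with columns
#' `gene_id`, `scaffold_id`, `start`, `end`, `exons`, `product`, where `exons`
#' is a semicolon-joined list of `start-end` intervals (empty = whole gene
#' span). Exon intervals are normalised: sorted, merged when overlapping or
#' book-ended; genes with no exon rows get a single exon equal to the gene
#' span. Coordinates are 1-based inclusive throughout.
#'
#' @param path path to annotation file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return tibble with columns `gene_id`, `scaffold_id`, `start`, `end`,
#'   `product` and a list-column `exons` of tibbles (`start`, `end`).
#' @export
read_gene_annotation <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  genes <- if (dialect == "tsv") read_genes_tsv(path) else read_genes_gff3(path)
  validate_gene_models(genes)
}

read_genes_tsv <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(), scaffold_id = readr::col_character(),
      start = readr::col_integer(), end = readr::col_integer(),
      exons = readr::col_character(), product = readr::col_character()
    )
  )
  df$exons <- purrr::pmap(df[c("exons", "start", "end")],
    function(exons, start, end) parse_exon_field(exons, start, end))
  df$product <- ifelse(is.na(df$product), "", df$product)
  df[c("gene_id", "scaffold_id", "start", "end", "product", "exons")]
}

parse_exon_field <- function(field, gene_start, gene_end) {
  if (is.na(field) || !nzchar(field)) {
    return(tibble(start = gene_start, end = gene_end))
  }
  parts <- strsplit(field, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)-(\\d+)$", parts))
  if (any(lengths(m) != 3)) abort(paste0("malformed exon field: ", field))
  tibble(
    start = as.integer(vapply(m, `[`, character(1), 2)),
    end = as.integer(vapply(m, `[`, character(1), 3))
  )
}

read_genes_gff3 <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), scaffold_id = character(),
                  start = integer(), end = integer(), product = character(),
                  exons = list()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) abort("malformed GFF3: expected 9 tab-separated fields")
  df <- tibble(
    scaffold_id = vapply(f, `[`, character(1), 1),
    type = vapply(f, `[`, character(1), 3),
    start = as.integer(vapply(f, `[`, character(1), 4)),
    end = as.integer(vapply(f, `[`, character(1), 5)),
    attrs = vapply(f, `[`, character(1), 9)
  )
  attr_of <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 3) x[[3]] else NA_character_,
           character(1))
  }
  genes <- df[df$type == "gene", ]
  genes$gene_id <- attr_of(genes$attrs, "ID")
  prod <- attr_of(genes$attrs, "product")
  note <- attr_of(genes$attrs, "Note")
  genes$product <- ifelse(!is.na(prod), prod, ifelse(!is.na(note), note, ""))
  mrna <- df[df$type == "mRNA", ]
  mrna_parent <- setNames(attr_of(mrna$attrs, "Parent"), attr_of(mrna$attrs, "ID"))
  exons <- df[df$type == "exon", ]
  exon_parent <- attr_of(exons$attrs, "Parent")
  # exons may hang off an mRNA or directly off the gene
  exon_gene <- ifelse(exon_parent %in% names(mrna_parent),
                      mrna_parent[exon_parent], exon_parent)
  genes$exons <- lapply(seq_len(nrow(genes)), function(i) {
    sel <- which(exon_gene == genes$gene_id[[i]])
    if (length(sel) == 0) {
      tibble(start = genes$start[[i]], end = genes$end[[i]])
    } else {
      tibble(start = exons$start[sel], end = exons$end[sel])
    }
  })
  genes[c("gene_id", "scaffold_id", "start", "end", "product", "exons")]
}

validate_gene_models <- function(genes) {
  if (nrow(genes) == 0) return(genes)
  if (any(genes$end < genes$start)) {
    bad <- genes$gene_id[which(genes$end < genes$start)[1]]
    abort(paste0("gene ", bad, ": end < start"))
  }
  genes$exons <- purrr::pmap(genes[c("gene_id", "start", "end", "exons")],
    function(gene_id, start, end, exons) {
      if (any(exons$end < exons$start)) {
        abort(paste0("gene ", gene_id, ": exon end < start"))
      }
      if (any(exons$start < start | exons$end > end)) {
        abort(paste0("gene ", gene_id, ": exon outside gene span"))
      }
      r <- IRanges::reduce(IRanges::IRanges(exons$start, exons$end),
                           min.gapwidth = 1L)
      tibble(start = IRanges::start(r), end = IRanges::end(r))
    })
  genes
}

#' Read a SNP table
#'
#' Reads single-nucleotide variants from a VCF v4 subset (columns
#' `CHROM POS ID REF ALT`, remaining columns ignored) or a TSV with columns
#' `scaffold_id`, `position`, `ref`, `alt`. Positions are 1-based in both
#' dialects. Multi-allelic rows are expanded to one record per alternate
#' allele; rows whose ref or alt allele is not a single base (indels) are
#' skipped and counted in the `n_skipped_indels` attribute.
#'
#' @param path path to the SNP file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return tibble with columns `scaffold_id`, `position`, `ref`, `alt`;
#'   attribute `n_skipped_indels` carries the skip counter.
#' @export
read_snp_table <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(
      scaffold_id = readr::col_character(),
      position = readr::col_character(),
      ref = readr::col_character(), alt = readr::col_character()
    ))
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (length(f) > 0 && any(lengths(f) < 5)) {
      abort("malformed VCF: expected at least 5 tab-separated fields")
    }
    df <- tibble(
      scaffold_id = vapply(f, `[`, character(1), 1),
      position = vapply(f, `[`, character(1), 2),
      ref = vapply(f, `[`, character(1), 4),
      alt = vapply(f, `[`, character(1), 5)
    )
  }
  pos <- suppressWarnings(as.integer(df$position))
  if (nrow(df) > 0 && any(is.na(pos))) {
    abort(sprintf("non-numeric position '%s'", df$position[which(is.na(pos))[1]]))
  }
  df$position <- pos
  if (any(df$position < 1, na.rm = TRUE)) abort("positions must be >= 1")
  # expand multi-allelic alts, then drop indel rows
  df <- tidyr::separate_rows(df, "alt", sep = ",")
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  is_snp <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0) {
    inform(sprintf("read_snp_table: skipped %d non-SNP allele row(s)", n_skipped))
  }
  df <- df[is_snp, , drop = FALSE]
  if (any(df$ref == df$alt)) abort("ref and alt alleles must differ")
  out <- as_tibble(df[c("scaffold_id", "position", "ref", "alt")])
  attr(out, "n_skipped_indels") <- n_skipped
  out
}

#' Write SNPs as a minimal VCF subset
#' @param snps tibble with `scaffold_id`, `position`, `ref`, `alt`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  snps$scaffold_id, snps$position, snps$ref, snps$alt)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

# fixed column contract of the marker database
MARKER_DB_COLUMNS <- c(
  "primer_name", "repeat_type", "repeat_sequence", "repeat_size",
  "repeat_start", "repeat_end", "forward_seq", "reverse_seq",
  "annealing_temperature", "gc_percent", "product_size", "scaffold_id",
  "gene_product", "gene_start", "gene_end", "snp_positions"
)

#' Write the marker database
#'
#' Tab-separated, one header line, columns in the fixed marker-database order.
#' `snp_positions` (a list-column of integer vectors) is serialised as
#' semicolon-joined positions; missing fields become empty strings.
#'
#' @param rows marker database tibble (see [build_marker_database()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_primer_database <- function(rows, path) {
  missing_cols <- setdiff(MARKER_DB_COLUMNS, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0("missing database columns: ", paste(missing_cols, collapse = ", ")))
  }
  out <- rows[MARKER_DB_COLUMNS]
  out$snp_positions <- vapply(out$snp_positions, function(p) {
    if (is.null(p) || length(p) == 0) "" else paste(p, collapse = ";")
  }, character(1))
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a marker database written by [write_primer_database()]
#' @param path path to the TSV.
#' @return tibble in the fixed column order, `snp_positions` as a list-column
#'   of integer vectors.
#' @export
read_primer_database <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character(),
    repeat_size = readr::col_integer(),
    repeat_start = readr::col_integer(), repeat_end = readr::col_integer(),
    annealing_temperature = readr::col_double(),
    product_size = readr::col_integer(),
    gene_start = readr::col_integer(), gene_end = readr::col_integer()
  ), na = "")
  df$gene_product <- ifelse(is.na(df$gene_product), "", df$gene_product)
  df$snp_positions <- lapply(df$snp_positions, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  as_tibble(df[MARKER_DB_COLUMNS])
}

#' Filter the marker database by gene-product keywords
#'
#' Case-insensitive substring match of any keyword against the `gene_product`
#' field, the query used to pull markers inside e.g. disease-resistance
#' related genes. Row order is preserved. The number of distinct gene spans
#' matched is attached as attribute `n_genes`.
#'
#' @param rows marker database tibble.
#' @param keywords character vector of keywords; empty vector matches nothing.
#' @return the matching subset, with attribute `n_genes`.
#' @export
filter_by_gene_product <- function(rows, keywords) {
  if (length(keywords) == 0) {
    out <- rows[0, , drop = FALSE]
    attr(out, "n_genes") <- 0L
    return(out)
  }
  prod_lc <- tolower(rows$gene_product %||% character(nrow(rows)))
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k) {
    grepl(k, prod_lc, fixed = TRUE)
  }))
  hit[is.na(hit)] <- FALSE
  out <- rows[hit, , drop = FALSE]
  genes <- unique(paste(out$scaffold_id, out$gene_start, out$gene_end))
  attr(out, "n_genes") <- length(genes)
  out
}
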
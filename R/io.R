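# Shared readers/writers.  Tabular outputs carry '#'-prefixed header
# comments recording the schema version and generating seed; readers skip
# them.  Floating-point columns are serialized at 6 decimals for
# reproducible diffs.

.io_header <- function(schema, seed = NULL) {
  c(paste0("# schema: ", schema, "/1"),
    if (!is.null(seed)) paste0("# seed: ", seed))
}

.fmt_num <- function(d) {
  for (nm in names(d))
    if (is.double(d[[nm]])) d[[nm]] <- round(d[[nm]], 6)
  d
}

.write_table <- function(d, path, schema, seed = NULL, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.io_header(schema, seed), con)
  utils::write.table(.fmt_num(d), con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.read_table <- function(path, sep = ",", need = character(0), ...) {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         comment.char = "#", stringsAsFactors = FALSE, ...)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("malformed file ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  d
}

#' Write / read a longitudinal VAF table (CSV)
#'
#' Columns: `variant`, `time_months`, `vaf`, `droplets`, plus an optional
#' `censored` flag (reconstructed from the detection limit when absent).
#'
#' @param vaf Long data.frame as produced by
#'   [simulate_clonal_trajectories()].
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @return `write_vaf_csv`: the path, invisibly. `read_vaf_csv`: the
#'   data.frame.
#' @export
write_vaf_csv <- function(vaf, path, seed = NULL) {
  .write_table(vaf, path, "vaf", seed, sep = ",")
}

#' @rdname write_vaf_csv
#' @param detection_limit VAF floor used to rebuild a missing `censored`
#'   column.
#' @export
read_vaf_csv <- function(path, detection_limit = 0.001) {
  d <- .read_table(path, sep = ",",
                   need = c("variant", "time_months", "vaf", "droplets"))
  if (any(d$vaf < 0 | d$vaf > 1)) stop("malformed VAF outside [0,1]")
  for (v in unique(d$variant)) {
    tt <- d$time_months[d$variant == v]
    if (is.unsorted(tt, strictly = TRUE))
      stop("times not strictly increasing for variant ", v)
  }
  if (is.null(d$censored)) d$censored <- d$vaf < detection_limit
  d
}

#' Write / read a colony genotype table (TSV)
#'
#' @param genotypes data.frame from [simulate_colonies()].
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @export
write_colony_tsv <- function(genotypes, path, seed = NULL) {
  .write_table(genotypes, path, "colonies", seed, sep = "\t")
}

#' @rdname write_colony_tsv
#' @export
read_colony_tsv <- function(path) {
  .read_table(path, sep = "\t", need = c("colony", "compartment", "clone"))
}

#' Write / read a binary colony x variant mutation matrix (TSV)
#'
#' Colonies as rows; leading metadata columns `colony`, `compartment`,
#' `age_years`, then one 0/1 column per variant (`NA` = not genotyped).
#' Intended for matrices of study size (trunk + private variants of tens
#' to hundreds of colonies).
#'
#' @param mm A [mutation_matrix()].
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @export
write_mutation_matrix_tsv <- function(mm, path, seed = NULL) {
  stopifnot(inherits(mm, "mutation_matrix"))
  m <- as.matrix(mm$matrix)
  if (!is.null(mm$missing) && nrow(mm$missing) > 0)
    m[mm$missing] <- NA
  d <- data.frame(colony = mm$colonies,
                  compartment = if (is.null(mm$compartment)) "NA"
                                else mm$compartment,
                  age_years = if (is.null(mm$age_years)) NA
                              else mm$age_years,
                  stringsAsFactors = FALSE, check.names = FALSE)
  d <- cbind(d, as.data.frame(m, check.names = FALSE))
  .write_table(d, path, "mutation_matrix", seed, sep = "\t")
}

#' @rdname write_mutation_matrix_tsv
#' @export
read_mutation_matrix_tsv <- function(path) {
  d <- .read_table(path, sep = "\t", need = c("colony"), check.names = FALSE)
  meta <- intersect(c("colony", "compartment", "age_years"), names(d))
  m <- as.matrix(d[setdiff(names(d), meta)])
  rownames(m) <- d$colony
  mutation_matrix(m,
                  compartment = if ("compartment" %in% meta) d$compartment,
                  age_years = if ("age_years" %in% meta) d$age_years)
}

#' Write / read junction counts (MatrixMarket + BED sidecar + cell TSV)
#'
#' Writes three files under `prefix`: `<prefix>.mtx` (sparse counts,
#' cells x junctions), `<prefix>.junctions.bed` (BED6 + a `kind` column,
#' 0-based half-open) and `<prefix>.cells.tsv` (cell id, genotype).
#'
#' @param tab A [junction_count_table()].
#' @param prefix Path prefix for the three files.
#' @param seed Seed recorded in the cell-table header.
#' @export
write_junction_counts <- function(tab, prefix, seed = NULL) {
  stopifnot(inherits(tab, "junction_count_table"))
  sm <- methods::as(Matrix::Matrix(tab$counts, sparse = TRUE),
                    "generalMatrix")
  Matrix::writeMM(sm, paste0(prefix, ".mtx"))
  bed <- data.frame(chrom = tab$junctions$chrom,
                    start = tab$junctions$start,
                    end = tab$junctions$end,
                    name = tab$junctions$junction_id,
                    score = 0L,
                    strand = tab$junctions$strand,
                    kind = tab$junctions$kind,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, paste0(prefix, ".junctions.bed"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  .write_table(tab$cells, paste0(prefix, ".cells.tsv"), "cells", seed,
               sep = "\t")
  invisible(prefix)
}

#' @rdname write_junction_counts
#' @export
read_junction_counts <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  bed <- utils::read.table(paste0(prefix, ".junctions.bed"), sep = "\t",
                           stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand",
                  "kind")[seq_len(ncol(bed))]
  if (is.null(bed$kind)) bed$kind <- "junction"
  jx <- junction_record(bed$chrom, bed$start, bed$end, bed$strand, bed$kind)
  if (!identical(jx$junction_id, bed$name))
    stop("junction BED names inconsistent with coordinates")
  cells <- .read_table(paste0(prefix, ".cells.tsv"), sep = "\t",
                       need = c("cell_id", "genotype"))
  if (nrow(m) != nrow(cells) || ncol(m) != nrow(jx))
    stop("junction count matrix dimensions disagree with sidecars")
  dimnames(m) <- list(cells$cell_id, jx$junction_id)
  junction_count_table(m, jx, cells$genotype)
}

#' Write / read transcript annotation (GTF)
#'
#' The package works in 0-based half-open coordinates; GTF is 1-based
#' closed.  `write_annotation_gtf` converts outgoing intervals
#' (`start + 1`, `end`), `read_annotation_gtf` converts incoming ones
#' back (`start - 1`, `end`), so a round trip is drift-free.  Parsing and
#' serialization go through `rtracklayer`.
#'
#' @param annotation data.frame with `chrom`, `start`, `end`, `strand`,
#'   `feature` (exon/CDS), `gene_id`, `transcript_id` (0-based
#'   half-open).
#' @param path File path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1,
                              end = annotation$end),
    strand = annotation$strand,
    type = annotation$feature,
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id,
    phase = ifelse(annotation$feature == "CDS", 0L, NA_integer_))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  feature = as.character(gr$type),
                  gene_id = gr$gene_id,
                  transcript_id = gr$transcript_id,
                  stringsAsFactors = FALSE)
  d[d$feature %in% c("exon", "CDS"), , drop = FALSE]
}

#' Write a JSON report with seed and schema metadata
#'
#' @param x List to serialize.
#' @param path File path.
#' @param seed Seed recorded in the payload.
#' @export
write_json_report <- function(x, path, seed = NULL) {
  x$schema <- "report/1"
  if (!is.null(seed)) x$seed <- seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_report
#' @export
read_json_report <- function(path) jsonlite::read_json(path,
                                                       simplifyVector = TRUE)
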
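#' Construct a junction count table
#'
#' Rows are cells (or pseudobulk groups) with a genotype label, columns
#' are junctions keyed by intron bounds (0-based half-open).  Genotype
#' labels are free-form but the splice workflow expects mutant clones
#' (`cloneA`, `cloneB`, ...), `WT`, and control donor ids (`control1`,
#' ...).
#'
#' @param counts Integer matrix (cells x junctions); column names must
#'   match `junctions$junction_id`.
#' @param junctions Junction table from [junction_record()].
#' @param genotype Per-row genotype label.
#' @return Object of class `junction_count_table`.
#' @export
junction_count_table <- function(counts, junctions, genotype) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative junction counts")
  if (anyDuplicated(junctions$junction_id)) stop("junction keys not unique")
  if (!identical(colnames(counts), junctions$junction_id))
    stop("count columns must match junction table keys")
  if (length(genotype) != nrow(counts) || anyNA(genotype))
    stop("every row needs a genotype label")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%04d", seq_len(nrow(counts)))
  structure(list(counts = counts, junctions = junctions,
                 cells = data.frame(cell_id = rownames(counts),
                                    genotype = genotype,
                                    stringsAsFactors = FALSE)),
            class = "junction_count_table")
}

#' @export
print.junction_count_table <- function(x, ...) {
  cat("junction_count_table:", nrow(x$counts), "rows x", ncol(x$counts),
      "junctions; groups:",
      paste(names(table(x$cells$genotype)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.junction_count_table <- function(x) dim(x$counts)
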
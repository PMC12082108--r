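#' Build a junction record table
#'
#' Junctions are keyed by intron bounds in 0-based half-open coordinates:
#' `chrom:start-end:strand`.  `kind` distinguishes true splice junctions
#' from intron-retention proxy rows (intronic-coverage counts emitted by
#' the generator), which get a `:RI` key suffix so keys stay unique.
#'
#' @param chrom,start,end,strand Vectors of junction coordinates.
#' @param kind `"junction"` or `"intron_proxy"`.
#' @return data.frame with a `junction_id` key column.
#' @export
junction_record <- function(chrom, start, end, strand = "+",
                            kind = "junction") {
  stopifnot(all(end > start), all(start >= 0),
            all(strand %in% c("+", "-")),
            all(kind %in% c("junction", "intron_proxy")))
  n <- max(length(chrom), length(start))
  d <- data.frame(chrom = rep_len(chrom, n), start = rep_len(start, n),
                  end = rep_len(end, n), strand = rep_len(strand, n),
                  kind = rep_len(kind, n), stringsAsFactors = FALSE)
  d$junction_id <- paste0(d$chrom, ":", d$start, "-", d$end, ":", d$strand,
                          ifelse(d$kind == "intron_proxy", ":RI", ""))
  d[c("junction_id", "chrom", "start", "end", "strand", "kind")]
}

#' Construct a splicing event from inclusion/exclusion junction sets
#'
#' An event pairs the junctions whose reads support the (cryptic)
#' inclusion form with those supporting the canonical/exclusion form.
#' The event type is derived from junction geometry via
#' [classify_event()] unless supplied.
#'
#' @param event_id,gene_id Identifiers.
#' @param inclusion,exclusion Junction tables from [junction_record()].
#' @param annotation Optional annotation table (see
#'   [read_annotation_gtf()]) used for SE/MXE exon checks.
#' @param event_type Optional known type; checked against geometry if the
#'   geometry is classifiable.
#' @return Object of class `splice_event`.
#' @export
splice_event <- function(event_id, gene_id, inclusion, exclusion,
                         annotation = NULL, event_type = NULL) {
  if (length(intersect(inclusion$junction_id, exclusion$junction_id)))
    stop("inclusion and exclusion junction sets must be disjoint")
  cls <- classify_event(inclusion, exclusion, annotation)
  if (is.null(event_type)) event_type <- cls$event_type
  structure(list(event_id = event_id, gene_id = gene_id,
                 event_type = event_type,
                 inclusion = inclusion, exclusion = exclusion,
                 offset = cls$offset, cryptic_site = cls$cryptic_site,
                 canonical_site = cls$canonical_site,
                 chrom = inclusion$chrom[1], strand = inclusion$strand[1]),
            class = "splice_event")
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("splice_event %s [%s] gene %s: %d inclusion / %d exclusion junctions, offset %s nt\n",
              x$event_id, x$event_type, x$gene_id, nrow(x$inclusion),
              nrow(x$exclusion), format(x$offset)))
  invisible(x)
}

#' Classify a splicing event from junction geometry
#'
#' Applies the standard geometric rules, in 0-based half-open intron
#' coordinates where `start` is the 5' (donor) boundary on the plus
#' strand and the 3' (acceptor) boundary on the minus strand:
#' * two junctions sharing `start` differ at the 3' splice site on the
#'   plus strand (A3SS) and at the 5' site on the minus strand (A5SS);
#'   sharing `end` is the mirror case;
#' * one exclusion junction spanning an (annotated) internal exon flanked
#'   by two inclusion junctions is exon skipping (SE);
#' * two junction pairs sharing outer boundaries but splicing in disjoint
#'   internal exons are mutually exclusive exons (MXE);
#' * an intron-retention proxy row paired with the matching spliced
#'   junction is intron retention (RI).
#'
#' @param inclusion,exclusion Junction tables ([junction_record()]).
#' @param annotation Optional annotation; when supplied, SE/MXE require
#'   the internal exon(s) to be annotated.
#' @return List with `event_type` (`"unclassified"` if no rule matches),
#'   `offset` (nt between cryptic and canonical sites), `cryptic_site`,
#'   `canonical_site`.
#' @export
classify_event <- function(inclusion, exclusion, annotation = NULL) {
  un <- list(event_type = "unclassified", offset = NA_real_,
             cryptic_site = NA_real_, canonical_site = NA_real_)
  all_j <- rbind(inclusion, exclusion)
  if (length(unique(all_j$chrom)) != 1 || length(unique(all_j$strand)) != 1)
    return(un)
  strand <- all_j$strand[1]
  chrom <- all_j$chrom[1]
  exon_annotated <- function(s, e) {
    if (is.null(annotation)) return(TRUE)
    any(annotation$feature == "exon" & annotation$chrom == chrom &
          annotation$start == s & annotation$end == e)
  }
  # intron retention: proxy coverage row vs its spliced junction
  if (any(inclusion$kind == "intron_proxy")) {
    pr <- inclusion[inclusion$kind == "intron_proxy", ][1, ]
    hit <- exclusion$kind == "junction" &
      exclusion$start == pr$start & exclusion$end == pr$end
    if (any(hit))
      return(list(event_type = "RI", offset = pr$end - pr$start,
                  cryptic_site = pr$start, canonical_site = pr$start))
    return(un)
  }
  ni <- nrow(inclusion); ne <- nrow(exclusion)
  if (ni == 1 && ne == 1) {
    i <- inclusion[1, ]; e <- exclusion[1, ]
    if (i$start == e$start && i$end != e$end) {
      type <- if (strand == "+") "A3SS" else "A5SS"
      return(list(event_type = type, offset = abs(i$end - e$end),
                  cryptic_site = i$end, canonical_site = e$end))
    }
    if (i$end == e$end && i$start != e$start) {
      type <- if (strand == "+") "A5SS" else "A3SS"
      return(list(event_type = type, offset = abs(i$start - e$start),
                  cryptic_site = i$start, canonical_site = e$start))
    }
    return(un)
  }
  if (ni == 2 && ne == 1) {
    inc <- inclusion[order(inclusion$start), ]
    e <- exclusion[1, ]
    if (e$start == inc$start[1] && e$end == inc$end[2] &&
        inc$end[1] < inc$start[2] &&
        exon_annotated(inc$end[1], inc$start[2])) {
      len <- inc$start[2] - inc$end[1]
      return(list(event_type = "SE", offset = len,
                  cryptic_site = inc$end[1], canonical_site = inc$end[1]))
    }
    return(un)
  }
  if (ni == 2 && ne == 2) {
    inc <- inclusion[order(inclusion$start), ]
    exc <- exclusion[order(exclusion$start), ]
    ex_i <- c(inc$end[1], inc$start[2])
    ex_e <- c(exc$end[1], exc$start[2])
    disjoint <- ex_i[2] <= ex_e[1] || ex_e[2] <= ex_i[1]
    if (inc$start[1] == exc$start[1] && inc$end[2] == exc$end[2] &&
        ex_i[1] < ex_i[2] && ex_e[1] < ex_e[2] && disjoint &&
        exon_annotated(ex_i[1], ex_i[2]) && exon_annotated(ex_e[1], ex_e[2])) {
      return(list(event_type = "MXE",
                  offset = abs((ex_i[2] - ex_i[1]) - (ex_e[2] - ex_e[1])),
                  cryptic_site = ex_i[1], canonical_site = ex_e[1]))
    }
    return(un)
  }
  un
}

#' Annotate the predicted coding consequence of a cryptic event
#'
#' Locates the event's canonical splice site relative to the CDS span of
#' overlapping annotated transcripts: inside the CDS, the cryptic/
#' canonical offset decides frame preservation (`offset mod 3 == 0` is an
#' in-frame insertion/deletion, otherwise frameshift/truncating); events
#' whose affected site lies wholly in UTR or non-coding sequence are
#' `"noncoding"`; events with no overlapping transcript are
#' `"unannotated"`.
#'
#' @param event A [splice_event()].
#' @param annotation Annotation table with `exon` and `CDS` features
#'   (0-based half-open; see [read_annotation_gtf()]).
#' @return One of `"in-frame"`, `"frameshift"`, `"noncoding"`,
#'   `"unannotated"`.
#' @export
annotate_consequence <- function(event, annotation) {
  stopifnot(inherits(event, "splice_event"))
  lo <- min(event$inclusion$start, event$exclusion$start)
  hi <- max(event$inclusion$end, event$exclusion$end)
  # junction endpoints abut exons, so touching intervals count as overlap
  ann <- annotation[annotation$chrom == event$chrom &
                      annotation$start <= hi & annotation$end >= lo, ,
                    drop = FALSE]
  if (nrow(ann) == 0) return("unannotated")
  site <- event$canonical_site
  for (tx in unique(ann$transcript_id)) {
    cds <- annotation[annotation$transcript_id == tx &
                        annotation$feature == "CDS", , drop = FALSE]
    if (nrow(cds) == 0) next
    span <- c(min(cds$start), max(cds$end))
    if (site >= span[1] && site < span[2]) {
      if (is.na(event$offset)) return("unannotated")
      return(if (event$offset %% 3 == 0) "in-frame" else "frameshift")
    }
  }
  "noncoding"
}
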
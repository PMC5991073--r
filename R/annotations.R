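#' Load miRNA annotation records from GFF3 or BED
#'
#' Reads miRNA coordinates in miRBase style. GFF3 records are filtered to the
#' requested feature types (hairpin-scale records by default); BED input is
#' 0-based half-open and is converted to the 1-based fully-closed convention
#' used throughout the package at this boundary. Duplicate miRNA names are
#' rejected because downstream results are keyed by name.
#'
#' @param path annotation file path.
#' @param format `"gff3"` or `"bed"`.
#' @param feature_types GFF3 feature types to keep. The default accepts both
#'   `miRNA_primary_transcript` (miRBase hairpin records) and `miRNA`;
#'   restrict to one type when loading a full miRBase GFF3 that also carries
#'   mature-miRNA records.
#' @return data frame with columns `name`, `chrom`, `tx_start`, `tx_end`
#'   (1-based inclusive).
#' @export
load_mirna_annotations <- function(path, format = c("gff3", "bed"),
                                   feature_types = c("miRNA_primary_transcript", "miRNA")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  empty <- data.frame(name = character(), chrom = character(),
                      tx_start = integer(), tx_end = integer(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (all(grepl("^\\s*$", lines) | startsWith(lines, "#"))) return(empty)
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse ", format, " file '", path, "': ",
                             conditionMessage(e))
  )
  if (length(gr) == 0) return(empty)
  md <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    keep <- as.character(md$type) %in% feature_types
    gr <- gr[keep]
    md <- S4Vectors::mcols(gr)
    if (length(gr) == 0) return(empty)
    nm <- if ("Name" %in% names(md)) as.character(md$Name) else as.character(md$ID)
  } else {
    nm <- as.character(md$name)
  }
  if (anyNA(nm) || any(nm == "")) stop("annotation records without a name in ", path)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    stop("duplicate miRNA names in ", path, ": ", paste(utils::head(dup, 5), collapse = ", "))
  }
  data.frame(name = nm,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             tx_start = GenomicRanges::start(gr),
             tx_end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Keep only autosomal annotation records
#'
#' Retains records whose chromosome label parses to 1-22 (with or without a
#' "chr" prefix) and reports how many records were removed. Labels other than
#' 1-22, X, Y or MT are treated as errors rather than silently dropped.
#'
#' @param records data frame as returned by [load_mirna_annotations()].
#' @return list with `records` (autosomal subset) and `n_removed`.
#' @export
filter_autosomal <- function(records) {
  if (nrow(records) == 0) return(list(records = records, n_removed = 0L))
  chrom <- norm_chrom(records$chrom)
  bad <- !(chrom %in% .known_chroms)
  if (any(bad)) {
    stop("unrecognized chromosome label(s): ",
         paste(unique(records$chrom[bad]), collapse = ", "))
  }
  keep <- chrom %in% .autosomes
  out <- records[keep, , drop = FALSE]
  out$chrom <- chrom[keep]
  rownames(out) <- NULL
  list(records = out, n_removed = sum(!keep))
}

#' Expand miRNA transcripts into flanked test windows
#'
#' The test window is the full transcript plus `flank_bp` on each side
#' (symmetric; strand is ignored), clamped at position 1. The 20 kb default
#' covers the majority of proximal regulatory sequence.
#'
#' @param records data frame with `name`, `chrom`, `tx_start`, `tx_end`.
#' @param flank_bp flanking length in bp (default 20000).
#' @return the input with added columns `win_start`, `win_end` (1-based
#'   inclusive).
#' @export
expand_window <- function(records, flank_bp = 20000) {
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  if (nrow(records) > 0 && any(records$tx_start > records$tx_end)) {
    stop("tx_start > tx_end in annotation records")
  }
  records$win_start <- pmax(1, records$tx_start - flank_bp)
  records$win_end <- records$tx_end + flank_bp
  records
}

#' Assign summary-statistic SNPs to miRNA windows
#'
#' A SNP belongs to a window iff it lies on the same chromosome and its
#' position falls in the closed interval `[win_start, win_end]`. A SNP may
#' belong to several overlapping windows. Windows with no assigned SNP are
#' flagged `covered = FALSE` (not testable with these summary statistics).
#' Assignment is independent of input record order: each window's SNPs are
#' sorted by position, with ties broken by id.
#'
#' @param windows data frame from [expand_window()].
#' @param summary_stats data frame with columns `SNP`, `CHR`, `BP`, `P`.
#' @return list with `sets` (one element per window: `window` row, `snp_ids`,
#'   `covered`) and `n_covered`.
#' @export
assign_snps <- function(windows, summary_stats) {
  req <- c("SNP", "CHR", "BP", "P")
  if (!all(req %in% names(summary_stats))) {
    stop("summary_stats needs columns: ", paste(req, collapse = ", "))
  }
  snp_chrom <- norm_chrom(summary_stats$CHR)
  win_chrom <- norm_chrom(windows$chrom)
  sets <- vector("list", nrow(windows))
  if (nrow(windows) > 0) {
    win_gr <- GenomicRanges::GRanges(win_chrom,
                                     IRanges::IRanges(windows$win_start, windows$win_end))
    snp_gr <- GenomicRanges::GRanges(snp_chrom,
                                     IRanges::IRanges(summary_stats$BP, width = 1))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(win_gr, snp_gr))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (i in seq_len(nrow(windows))) {
      idx <- sh[qh == i]
      idx <- idx[order(summary_stats$BP[idx], summary_stats$SNP[idx])]
      sets[[i]] <- list(window = windows[i, , drop = FALSE],
                        snp_ids = summary_stats$SNP[idx],
                        covered = length(idx) > 0)
    }
  }
  names(sets) <- windows$name
  list(sets = sets, n_covered = sum(vapply(sets, `[[`, logical(1), "covered")))
}
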
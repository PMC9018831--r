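#' @include AllGenerics.R
NULL

# Coordinates are 0-based half-open throughout; bin index = floor(pos / res).

#' Bin index of a genomic position
#'
#' @param pos 0-based position(s) in bp.
#' @param resolution bin width in bp.
#' @return integer bin index (0-based).
#' @export
binIndex <- function(pos, resolution) floor(pos / resolution)

# Coerce any (dense/sparse, full-symmetric or upper-stored) matrix to the
# canonical upper-triangular sparse storage.  A matrix with an empty lower
# triangle is taken as already upper-stored; otherwise symmetry is required.
.asUpperSparse <- function(m) {
  m <- as(as(as(Matrix(m, sparse = TRUE), "dMatrix"), "generalMatrix"),
          "CsparseMatrix")
  low <- Matrix::tril(m, -1)
  if (length(low@x) && any(low@x != 0)) {
    if (!Matrix::isSymmetric(m, tol = 1e-8))
      stop("contact matrix must be symmetric (or upper-triangular storage)")
    m <- Matrix::triu(m)
  }
  drop0(Matrix::triu(m))
}

#' Construct a ContactMap
#'
#' @param matrix square matrix (dense or sparse); either symmetric or with
#'   only the upper triangle filled.
#' @param chrom chromosome name.
#' @param resolution bin width in bp.
#' @param offsetBin index of the first bin.
#' @param state normalization state ("raw", "oe", "log", "log_oe").
#' @param totalContacts raw count total; computed from the matrix when NULL
#'   and state is "raw".
#' @return a \linkS4class{ContactMap}.
#' @export
ContactMap <- function(matrix, chrom, resolution, offsetBin = 0,
                       state = "raw", totalContacts = NULL) {
  up <- .asUpperSparse(matrix)
  if (is.null(totalContacts))
    totalContacts <- if (state == "raw") sum(up@x) else NA_real_
  new("ContactMap", chrom = chrom, resolution = resolution,
      offsetBin = offsetBin, matrix = up, state = state,
      totalContacts = totalContacts)
}

#' Construct a BinTrack
#'
#' @param values numeric vector of per-bin values.
#' @param chrom chromosome name.
#' @param startBin index of the first bin.
#' @param resolution bin width in bp.
#' @param feature feature label.
#' @param normalized whether values are already observed/genome-mean.
#' @return a \linkS4class{BinTrack}.
#' @export
BinTrack <- function(values, chrom, startBin = 0, resolution = 200,
                     feature = "signal", normalized = FALSE) {
  new("BinTrack", chrom = chrom, startBin = startBin, resolution = resolution,
      values = as.numeric(values), feature = feature, normalized = normalized)
}

#' Construct a StructureCallSet
#'
#' Anchors are half-open bin intervals at `resolution`.  For loops both
#' anchors are intervals on the genome (anchor1 left of anchor2); for
#' stripes anchor1 is the anchor interval and anchor2 the extent interval,
#' with `orientation` "vertical" (anchor at the smaller coordinate,
#' extending right) or "horizontal" (the converse).
#'
#' @param chrom chromosome name.
#' @param resolution bin width in bp of the coordinates.
#' @param calls data.frame with columns kind, anchor1_start, anchor1_end,
#'   anchor2_start, anchor2_end, orientation, score.
#' @return a \linkS4class{StructureCallSet}.
#' @export
StructureCallSet <- function(chrom, resolution, calls = NULL) {
  if (is.null(calls))
    calls <- data.frame(kind = character(), anchor1_start = numeric(),
                        anchor1_end = numeric(), anchor2_start = numeric(),
                        anchor2_end = numeric(), orientation = character(),
                        score = numeric())
  new("StructureCallSet", chrom = chrom, resolution = resolution,
      calls = as.data.frame(calls)[, .callColumns])
}

#' @rdname StructureCallSet
#' @param anchor1,anchor2 bin indices (single-bin anchors).
#' @param score enrichment scores.
#' @export
loopCallSet <- function(chrom, resolution, anchor1, anchor2, score = NA_real_) {
  n <- length(anchor1)
  a1 <- pmin(anchor1, anchor2); a2 <- pmax(anchor1, anchor2)
  StructureCallSet(chrom, resolution, data.frame(
    kind = rep("loop", n), anchor1_start = a1, anchor1_end = a1 + 1,
    anchor2_start = a2, anchor2_end = a2 + 1,
    orientation = rep("na", n), score = rep_len(score, n)))
}

# ---- contact-map text format ---------------------------------------------
# A cooler-dump-style plain-text pixel table.  One file can hold several
# (chrom, resolution) blocks, each introduced by a '#block' metadata line,
# followed by 'bin1<TAB>bin2<TAB>value' rows (upper triangle, 0-based bins
# relative to offset_bin = 0 of the block grid).

#' Write a ContactMap to a plain-text pixel table
#'
#' @param map a \linkS4class{ContactMap}.
#' @param path output file.
#' @param append add a block to an existing file instead of overwriting.
#' @return invisibly, the path.
#' @export
writeContactMap <- function(map, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  if (!append) writeLines("## microcast contact map v1", con)
  writeLines(sprintf(
    "#block\tchrom=%s\tresolution=%g\toffset_bin=%g\tn_bins=%d\tstate=%s\ttotal=%g",
    map@chrom, map@resolution, map@offsetBin, nrow(map@matrix), map@state,
    map@totalContacts), con)
  tr <- .sparseTriplets(map@matrix)
  if (nrow(tr))
    writeLines(sprintf("%d\t%d\t%.17g", tr$i - 1L, tr$j - 1L, tr$x), con)
  invisible(path)
}

.sparseTriplets <- function(m) {
  m <- as(m, "TsparseMatrix")
  o <- order(m@i, m@j)
  data.frame(i = m@i[o] + 1L, j = m@j[o] + 1L, x = m@x[o])
}

.parseBlockHeader <- function(line) {
  fields <- strsplit(sub("^#block\t", "", line), "\t")[[1]]
  kv <- strsplit(fields, "=")
  vals <- vapply(kv, `[`, character(1), 2)
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals
}

#' Read a ContactMap from a plain-text pixel table
#'
#' @param path file written by \code{\link{writeContactMap}}.
#' @param chrom chromosome to read.
#' @param resolution resolution (bp) to read.
#' @return a \linkS4class{ContactMap}.
#' @export
readContactMap <- function(path, chrom, resolution) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#block", lines)
  if (!length(hdr)) stop("not a microcast contact file (no #block headers): ", path)
  meta <- lapply(lines[hdr], .parseBlockHeader)
  avail <- vapply(meta, function(m) paste0(m[["chrom"]], "@", m[["resolution"]]),
                  character(1))
  want <- paste0(chrom, "@", format(resolution))
  hit <- which(vapply(meta, function(m)
    m[["chrom"]] == chrom && as.numeric(m[["resolution"]]) == resolution,
    logical(1)))
  if (!length(hit))
    stop("no block for ", chrom, " at resolution ", resolution,
         "; available: ", paste(avail, collapse = ", "))
  h <- hit[1]
  m <- meta[[h]]
  from <- hdr[h] + 1L
  to <- if (h < length(hdr)) hdr[h + 1] - 1L else length(lines)
  body <- lines[seq(from, to)][grep("^[0-9]", lines[seq(from, to)])]
  n <- as.integer(m[["n_bins"]])
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t"))
    mat <- sparseMatrix(i = as.integer(parts[, 1]) + 1L,
                        j = as.integer(parts[, 2]) + 1L,
                        x = as.numeric(parts[, 3]), dims = c(n, n))
  } else {
    mat <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                        dims = c(n, n))
  }
  ContactMap(mat, chrom = m[["chrom"]], resolution = as.numeric(m[["resolution"]]),
             offsetBin = as.numeric(m[["offset_bin"]]), state = m[["state"]],
             totalContacts = as.numeric(m[["total"]]))
}

# ---- signal tracks --------------------------------------------------------

#' Read a binned signal track from bigWig or bedGraph
#'
#' Each bin value is the mean of the base-pair signal over the bin, with
#' missing data contributing 0.  Coordinates are 0-based half-open.
#'
#' @param path bigWig (.bw/.bigwig) or bedGraph file.
#' @param chrom chromosome name.
#' @param start,end region in bp; `end - start` must be a multiple of
#'   `resolution`.
#' @param resolution bin width in bp.
#' @param feature feature label; defaults to the file name.
#' @return a \linkS4class{BinTrack}.
#' @export
readTrack <- function(path, chrom, start, end, resolution = 200,
                      feature = NULL) {
  if (start < 0 || end <= start)
    stop("coordinate error: need 0 <= start < end (got ", start, ", ", end, ")")
  if ((end - start) %% resolution != 0)
    stop("coordinate error: end - start must be a multiple of resolution")
  if (is.null(feature)) feature <- basename(path)
  isBigWig <- grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)
  if (isBigWig) {
    which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
    gr <- rtracklayer::import(path, format = "BigWig", which = which)
  } else {
    gr <- rtracklayer::import(path, format = "bedGraph")
  }
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  nb <- (end - start) / resolution
  vals <- numeric(nb)
  if (length(gr)) {
    s0 <- pmax(GenomicRanges::start(gr) - 1L, start)  # 0-based starts
    e0 <- pmin(GenomicRanges::end(gr), end)           # half-open ends
    keep <- e0 > s0
    s0 <- s0[keep]; e0 <- e0[keep]; sc <- gr$score[keep]
    if (length(s0)) {
      binsGr <- IRanges::IRanges(start = start + resolution * (seq_len(nb) - 1) + 1,
                                 width = resolution)
      sigGr <- IRanges::IRanges(start = s0 + 1, end = e0)
      ov <- IRanges::findOverlaps(binsGr, sigGr)
      if (length(ov)) {
        q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
        w <- IRanges::width(IRanges::pintersect(binsGr[q], sigGr[s]))
        contrib <- tapply(sc[s] * w, q, sum)
        vals[as.integer(names(contrib))] <- as.numeric(contrib) / resolution
      }
    }
  }
  BinTrack(vals, chrom = chrom, startBin = start %/% resolution,
           resolution = resolution, feature = feature)
}

#' Write a BinTrack as bedGraph
#'
#' @param track a \linkS4class{BinTrack}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeTrack <- function(track, path) {
  res <- track@resolution
  starts <- (track@startBin + seq_along(track@values) - 1) * res
  keep <- track@values != 0
  lines <- sprintf("%s\t%g\t%g\t%.17g", track@chrom, starts[keep],
                   starts[keep] + res, track@values[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Normalize a track by the genome-wide mean
#'
#' Divides each bin value by `genomeMean` (observed / genome-wide average)
#' and marks the track as normalized.
#'
#' @param track a \linkS4class{BinTrack}.
#' @param genomeMean positive genome-wide mean signal.
#' @return the normalized \linkS4class{BinTrack}.
#' @export
normalizeTrack <- function(track, genomeMean) {
  if (!is.numeric(genomeMean) || length(genomeMean) != 1 || genomeMean <= 0)
    stop("genomeMean must be a single positive number")
  new("BinTrack", chrom = track@chrom, startBin = track@startBin,
      resolution = track@resolution, values = track@values / genomeMean,
      feature = track@feature, normalized = TRUE)
}

# ---- structure call I/O ---------------------------------------------------

#' Write structure calls to BEDPE (loops) or BED (stripes)
#'
#' Loops are emitted as BEDPE with both anchors expanded to bp intervals and
#' the score in column 8; stripes as BED with orientation and extent interval
#' in extra columns.  All coordinates 0-based half-open.
#'
#' @param calls a \linkS4class{StructureCallSet} (one kind per file).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeStructures <- function(calls, path) {
  df <- calls@calls
  res <- calls@resolution
  kinds <- unique(df$kind)
  if (length(kinds) > 1)
    stop("mixed call kinds in one file are not supported; write separately")
  con <- file(path, "w")
  on.exit(close(con))
  if (!nrow(df) || kinds == "loop") {
    writeLines(sprintf("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tscore\tresolution=%g",
                       res), con)
    if (nrow(df))
      writeLines(sprintf("%s\t%g\t%g\t%s\t%g\t%g\t.\t%.17g",
                         calls@chrom, df$anchor1_start * res, df$anchor1_end * res,
                         calls@chrom, df$anchor2_start * res, df$anchor2_end * res,
                         df$score), con)
  } else {
    writeLines(sprintf("#chrom\tstart\tend\tname\tscore\torientation\textent_start\textent_end\tresolution=%g",
                       res), con)
    writeLines(sprintf("%s\t%g\t%g\t.\t%.17g\t%s\t%g\t%g",
                       calls@chrom, df$anchor1_start * res, df$anchor1_end * res,
                       df$score, df$orientation, df$anchor2_start * res,
                       df$anchor2_end * res), con)
  }
  invisible(path)
}

#' Read structure calls written by \code{writeStructures}
#'
#' @param path BEDPE (loops) or extended BED (stripes) file.
#' @param kind "loop" or "stripe"; inferred from the header when NULL.
#' @return a \linkS4class{StructureCallSet}.
#' @export
readStructures <- function(path, kind = NULL) {
  lines <- readLines(path)
  hdr <- lines[1]
  res <- as.numeric(sub(".*resolution=", "", hdr))
  if (is.null(kind))
    kind <- if (grepl("chrom1", hdr)) "loop" else "stripe"
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body))
    return(StructureCallSet(chrom = "NA", resolution = res))
  parts <- do.call(rbind, strsplit(body, "\t"))
  if (kind == "loop") {
    df <- data.frame(
      kind = "loop",
      anchor1_start = as.numeric(parts[, 2]) / res,
      anchor1_end = as.numeric(parts[, 3]) / res,
      anchor2_start = as.numeric(parts[, 5]) / res,
      anchor2_end = as.numeric(parts[, 6]) / res,
      orientation = "na", score = as.numeric(parts[, 8]))
    chrom <- parts[1, 1]
  } else {
    df <- data.frame(
      kind = "stripe",
      anchor1_start = as.numeric(parts[, 2]) / res,
      anchor1_end = as.numeric(parts[, 3]) / res,
      anchor2_start = as.numeric(parts[, 7]) / res,
      anchor2_end = as.numeric(parts[, 8]) / res,
      orientation = parts[, 6], score = as.numeric(parts[, 5]))
    chrom <- parts[1, 1]
  }
  StructureCallSet(chrom = chrom, resolution = res, calls = df)
}

#' Read an eQTL-TSS pair table
#'
#' Expects a TSV with columns chrom, variant_pos, tss_pos, gene, tissue
#' (0-based bp positions).
#'
#' @param path TSV file.
#' @return data.frame with those columns.
#' @export
readEqtlPairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("chrom", "variant_pos", "tss_pos", "gene", "tissue")
  if (!all(need %in% names(df)))
    stop("eQTL table must have columns: ", paste(need, collapse = ", "))
  df
}
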
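#' Read and write reactivity tables
#'
#' Reactivity tables are TSV files with columns \code{transcript_id},
#' \code{position} (1-based), then one column per sample named
#' \code{<group><replicate>} (e.g. \code{A1}, \code{B2}); missing values
#' are the literal \code{NA}.
#'
#' @param file path to a TSV file.
#' @return \code{readReactivityTable} returns a \linkS4class{ReactivitySet}.
#' @export
readReactivityTable <- function(file) {
  tab <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position")
  if (!all(need %in% colnames(tab)))
    stop("reactivity table must have transcript_id and position columns: ",
         file)
  samples <- setdiff(colnames(tab), need)
  if (length(samples) == 0L)
    stop("reactivity table has no sample columns: ", file)
  tab <- tab[order(match(tab$transcript_id, unique(tab$transcript_id)),
                   tab$position), , drop = FALSE]
  profiles <- lapply(split(tab, factor(tab$transcript_id,
                                       unique(tab$transcript_id))),
                     function(chunk) {
    m <- as.matrix(chunk[, samples, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- NULL
    m
  })
  ReactivitySet(profiles)
}

#' @rdname readReactivityTable
#' @param x a \linkS4class{ReactivitySet}.
#' @export
writeReactivityTable <- function(x, file) {
  rd <- SummarizedExperiment::rowData(x)
  out <- data.frame(transcript_id = rd$transcript_id,
                    position = rd$position,
                    SummarizedExperiment::assay(x, "reactivity"),
                    check.names = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a per-sample count table (Structure-Seq/SHAPE-Seq)
#'
#' TSV with columns \code{transcript_id}, \code{position},
#' \code{treated_count}, \code{treated_coverage}, \code{untreated_count},
#' \code{untreated_coverage}; one file per sample.
#'
#' @param file path to a TSV file.
#' @return named list of [countProfile()] objects, one per transcript.
#' @export
readCountTable <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "treated_count",
            "treated_coverage", "untreated_count", "untreated_coverage")
  if (!all(need %in% colnames(tab)))
    stop("count table is missing required columns: ", file)
  tab <- tab[order(match(tab$transcript_id, unique(tab$transcript_id)),
                   tab$position), , drop = FALSE]
  lapply(split(tab, factor(tab$transcript_id, unique(tab$transcript_id))),
         function(chunk)
    countProfile(chunk$transcript_id[1L], chunk$treated_count,
                 chunk$treated_coverage, chunk$untreated_count,
                 chunk$untreated_coverage))
}

#' @rdname readCountTable
#' @param counts a named list of [countProfile()] objects.
#' @export
writeCountTable <- function(counts, file) {
  out <- do.call(rbind, lapply(counts, function(cp)
    data.frame(transcript_id = cp$transcript,
               position = seq_along(cp$treated_count),
               treated_count = cp$treated_count,
               treated_coverage = cp$treated_coverage,
               untreated_count = cp$untreated_count,
               untreated_coverage = cp$untreated_coverage)))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a PARS count table
#'
#' TSV with columns \code{transcript_id}, \code{position}, \code{V1},
#' \code{S1}.
#'
#' @param file path to a TSV file.
#' @return named list per transcript with integer vectors \code{v1} and
#'   \code{s1}.
#' @export
readPARSTable <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "V1", "S1")
  if (!all(need %in% colnames(tab)))
    stop("PARS table is missing required columns: ", file)
  tab <- tab[order(match(tab$transcript_id, unique(tab$transcript_id)),
                   tab$position), , drop = FALSE]
  lapply(split(tab, factor(tab$transcript_id, unique(tab$transcript_id))),
         function(chunk) list(v1 = chunk$V1, s1 = chunk$S1))
}

#' Read/write candidate-region lists
#'
#' BED-like TSV with columns \code{transcript_id}, \code{start}, \code{end}
#' (and optionally \code{mean_d_within}). Unlike BED, coordinates are
#' 1-based and inclusive to match nucleotide numbering.
#'
#' @param file path to a TSV file.
#' @return data.frame of regions.
#' @export
readRegionTable <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "start", "end") %in% colnames(tab)))
    stop("region table must have transcript_id, start, end: ", file)
  tab
}

#' @rdname readRegionTable
#' @param regions data.frame with transcript_id, start, end columns.
#' @export
writeRegionTable <- function(regions, file) {
  write.table(regions, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export d-score profiles as a TSV
#'
#' Columns: transcript_id, position, d_within, d_between, delta_d.
#'
#' @param profiles a \linkS4class{DScoreProfiles} or list thereof.
#' @param file output path.
#' @export
writeDScoreTable <- function(profiles, file) {
  if (methods::is(profiles, "DScoreProfiles"))
    profiles <- list(profiles)
  out <- do.call(rbind, lapply(profiles, function(p)
    data.frame(transcript_id = p@transcript,
               position = seq_along(p@dWithin),
               d_within = p@dWithin, d_between = p@dBetween,
               delta_d = deltaD(p))))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
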
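#' @include features.R
#' @importFrom data.table fread fwrite
#' @importFrom jsonlite read_json write_json
NULL

#' Read an aligned-transcript event file
#'
#' Reads the tab-separated dialect produced by forced alignment: columns
#' \code{onset_s}, \code{duration_s}, \code{tier} (word or phoneme) and
#' \code{label}, with a header row. Events are split by tier and onsets are
#' validated to be strictly increasing within each tier; a malformed or
#' out-of-order row raises an error naming the line.
#'
#' @param path path to a .tsv event file.
#' @return named list of \linkS4class{EventStream} (zero-dimensional feature
#'   vectors; encoders attach vectors), one element per tier present.
#' @export
readEventFile <- function(path) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  lines <- readLines(path)
  stopIfNot(length(lines) >= 1L, "empty event file")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("onset_s", "duration_s", "tier", "label")
  stopIfNot(all(need %in% header),
            "event file must have columns onset_s, duration_s, tier, label")
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header)) {
      stop("malformed event row at line ", i, call. = FALSE)
    }
    stats::setNames(as.list(f), header)
  })
  onset <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", "onset_s")))
  dur <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", "duration_s")))
  bad <- which(!is.finite(onset) | !is.finite(dur))
  if (length(bad)) {
    stop("non-numeric onset/duration at line ", bad[1L] + 1L, call. = FALSE)
  }
  tier <- vapply(rows, `[[`, "", "tier")
  label <- vapply(rows, `[[`, "", "label")
  out <- list()
  for (tr in unique(tier)) {
    sel <- which(tier == tr)
    if (length(sel) > 1L && any(diff(onset[sel]) <= 0)) {
      off <- sel[which(diff(onset[sel]) <= 0)[1L] + 1L]
      stop("onsets not increasing in tier '", tr, "' at line ", off + 1L,
           call. = FALSE)
    }
    out[[tr]] <- EventStream(tr, onset[sel],
                             matrix(numeric(0), nrow = length(sel), ncol = 0L),
                             durations = dur[sel], labels = label[sel])
  }
  out
}

#' Write event streams to the aligned-transcript TSV dialect
#'
#' Numeric fields are written with 17 significant digits so a write-then-read
#' round trip preserves all events exactly.
#'
#' @param streams named list of \linkS4class{EventStream} (names are tiers).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEventFile <- function(streams, path) {
  lines <- "onset_s\tduration_s\ttier\tlabel"
  for (tr in names(streams)) {
    s <- streams[[tr]]
    lines <- c(lines, sprintf("%.17g\t%.17g\t%s\t%s",
                              s@onsets, s@durations, tr, s@labels))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read interval tiers from a Praat TextGrid
#'
#' Parses the long ("ooTextFile") TextGrid format and returns one event
#' stream per interval tier, keeping only intervals with non-empty labels.
#'
#' @param path path to a .TextGrid file.
#' @return named list of \linkS4class{EventStream}.
#' @export
readTextGrid <- function(path) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  grab <- function(line, pat) {
    sub(paste0("^\\s*", pat, "\\s*=\\s*"), "", line)
  }
  out <- list()
  tierName <- NULL
  xmin <- NA_real_; curDur <- NA_real_; label <- NA_character_
  onsets <- numeric(0); durs <- numeric(0); labs <- character(0)
  flush <- function() {
    if (!is.null(tierName) && length(onsets)) {
      out[[tierName]] <<- EventStream(
        tierName, onsets, matrix(numeric(0), length(onsets), 0L),
        durations = durs, labels = labs
      )
    }
    onsets <<- numeric(0); durs <<- numeric(0); labs <<- character(0)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("class\\s*=\\s*\"IntervalTier\"", ln)) {
      flush(); tierName <- NULL
    } else if (grepl("^\\s*name\\s*=", ln) && is.null(tierName)) {
      tierName <- gsub("\"", "", grab(ln, "name"))
    } else if (grepl("^\\s*xmin\\s*=", ln)) {
      xmin <- as.numeric(grab(ln, "xmin"))
    } else if (grepl("^\\s*xmax\\s*=", ln)) {
      xmax <- as.numeric(grab(ln, "xmax"))
      if (!is.na(xmin)) curDur <- xmax - xmin
    } else if (grepl("^\\s*text\\s*=", ln)) {
      label <- gsub("\"", "", grab(ln, "text"))
      if (nzchar(trimws(label)) && !is.null(tierName)) {
        onsets <- c(onsets, xmin)
        durs <- c(durs, get("curDur"))
        labs <- c(labs, trimws(label))
      }
    }
  }
  flush()
  out
}

## ---- plain-text result containers -----------------------------------------

writeMatrixTsv <- function(m, path) {
  data.table::fwrite(as.data.frame(m), path, sep = "\t")
  invisible(path)
}

readMatrixTsv <- function(path) {
  as.matrix(data.table::fread(path, sep = "\t"))
}

#' Write a simulated scenario to a plain-text container
#'
#' The container is a directory of named datasets: \code{design.tsv},
#' \code{test_design.tsv}, \code{column_map.tsv}, \code{responses.tsv},
#' \code{repeats.tsv} (repeat index in the first column),
#' \code{truth_weights_<space>.tsv}, \code{truth_fractions.tsv},
#' \code{labels_region.tsv} and a \code{scenario.json} sidecar of the
#' scenario parameters.
#'
#' @param sim list as returned by \code{\link{simulateScenario}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeScenarioContainer <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeMatrixTsv(sim$design@values, p("design.tsv"))
  writeMatrixTsv(sim$testDesign@values, p("test_design.tsv"))
  data.table::fwrite(sim$design@columnMap, p("column_map.tsv"), sep = "\t")
  writeMatrixTsv(sim$design@storyBounds, p("story_bounds.tsv"))
  writeMatrixTsv(sim$responses@values, p("responses.tsv"))
  rep3 <- sim$responses@repeats
  if (!is.null(rep3)) {
    flat <- do.call(rbind, lapply(seq_len(dim(rep3)[1]), function(r) {
      cbind(repeat_index = r, rep3[r, , ])
    }))
    writeMatrixTsv(flat, p("repeats.tsv"))
  }
  for (sp in names(sim$truth@weights)) {
    writeMatrixTsv(sim$truth@weights[[sp]],
                   p(sprintf("truth_weights_%s.tsv", sp)))
  }
  writeMatrixTsv(cbind(sim$truth@uniqueFractions,
                       shared = sim$truth@sharedFraction,
                       noise_sd = sim$truth@noiseSd),
                 p("truth_fractions.tsv"))
  writeLines(sim$responses@regionLabels, p("labels_region.tsv"))
  sc <- sim$scenario
  jsonlite::write_json(
    list(nStories = sc@nStories, storyLenS = sc@storyLenS, trS = sc@trS,
         wordRateHz = sc@wordRateHz, vocabSize = sc@vocabSize,
         dims = as.list(sc@dims), seed = sc@seed,
         targetCcHalf = sim$truth@targetCcHalf),
    p("scenario.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
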
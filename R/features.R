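#' @include AllClasses.R utils.R
NULL

#' Construct an event stream
#'
#' @param spaceName feature-space identifier.
#' @param onsets event onsets in seconds, strictly increasing.
#' @param vectors numeric matrix, one row per event.
#' @param durations event durations in seconds (default 0).
#' @param labels optional event labels.
#' @return an \linkS4class{EventStream}.
#' @export
EventStream <- function(spaceName, onsets, vectors,
                        durations = rep(0, length(onsets)),
                        labels = rep("", length(onsets))) {
  vectors <- as.matrix(vectors)
  if (length(onsets) == 0L) {
    vectors <- matrix(numeric(0), nrow = 0L, ncol = ncol(vectors))
  }
  new("EventStream",
    spaceName = as.character(spaceName), onsets = as.numeric(onsets),
    durations = as.numeric(durations), labels = as.character(labels),
    vectors = vectors
  )
}

## Windowed-sinc Lanczos kernel, cutoff in Hz, a lobes. Not renormalized.
lanczosKernel <- function(t, cutoffHz, nLobes) {
  x <- cutoffHz * t
  out <- numeric(length(x))
  inside <- abs(x) < nLobes & x != 0
  xi <- x[inside]
  out[inside] <- nLobes * sin(pi * xi) * sin(pi * xi / nLobes) / (pi^2 * xi^2)
  out[x == 0] <- 1
  out
}

#' Resample an event stream to the TR grid with a Lanczos filter
#'
#' Each TR sample is the kernel-weighted sum of the event feature vectors,
#' using a windowed-sinc (Lanczos) kernel evaluated at (event time - TR
#' time). The cutoff frequency defaults to the Nyquist frequency of the TR
#' rate (0.25 Hz at TR = 2 s) and the kernel has three lobes, the standard
#' anti-aliasing configuration for event-rate stimulus features. Kernel
#' weights are not renormalized per sample, so the operation is exactly
#' linear in the event vectors. TR sample times are taken at the midpoint of
#' each TR, (k - 1/2) * trS.
#'
#' @param stream an \linkS4class{EventStream}.
#' @param trS repetition time in seconds.
#' @param nTR number of TR samples to produce.
#' @param nLobes number of kernel lobes (default 3).
#' @param cutoffHz kernel cutoff frequency; default the TR-rate Nyquist.
#' @return numeric matrix, nTR x featureDim(stream).
#' @export
lanczosResample <- function(stream, trS, nTR, nLobes = 3,
                            cutoffHz = 1 / (2 * trS)) {
  stopIfNot(is(stream, "EventStream"), "stream must be an EventStream")
  stopIfNot(nTR > 0, "nTR must be positive")
  stopIfNot(nLobes >= 1, "nLobes must be >= 1")
  dim <- ncol(stream@vectors)
  trTimes <- (seq_len(nTR) - 0.5) * trS
  if (length(stream@onsets) == 0L) {
    return(matrix(0, nrow = nTR, ncol = dim))
  }
  ## kernel matrix: rows TRs, columns events
  dt <- outer(trTimes, stream@onsets, "-")
  w <- matrix(lanczosKernel(as.numeric(dt), cutoffHz, nLobes),
              nrow = nTR, ncol = length(stream@onsets))
  w %*% stream@vectors
}

## Shift a story-wise matrix later in time by `d` TRs, zero-padding the
## story-initial rows. No wrap-around across stories.
delayWithinStories <- function(x, bounds, d) {
  out <- matrix(0, nrow = nrow(x), ncol = ncol(x))
  for (i in seq_len(nrow(bounds))) {
    rows <- storyRows(bounds, i)
    n <- length(rows)
    if (d < n) {
      out[rows[(d + 1L):n], ] <- x[rows[seq_len(n - d)], , drop = FALSE]
    }
  }
  out
}

#' Build a z-scored, FIR-delayed design matrix
#'
#' Takes per-story TR-rate feature matrices for one or more feature spaces,
#' concatenates the stories, z-scores every column on the concatenated
#' training set, and then appends delayed copies of the standardized columns
#' (default delays 1-4 TRs) so that a linear model can absorb the shape of
#' the hemodynamic response. Delayed samples at story starts are zero: the
#' delay never wraps across story boundaries. When \code{scaling} is supplied
#' (the \code{scaling} of a training design) its means and scales are reused
#' verbatim, so held-out designs are standardized without touching held-out
#' statistics.
#'
#' @param perStory list of stories; each story is a named list mapping
#'   feature-space name to a (nTR_story x dim) matrix. All stories must share
#'   spaces and dims.
#' @param trS repetition time in seconds.
#' @param delaysTr integer delays in TR units (default 1:4).
#' @param scaling optional scaling list from a previously built design.
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(perStory, trS, delaysTr = 1:4, scaling = NULL) {
  stopIfNot(length(perStory) >= 1L, "need at least one story")
  spaces <- names(perStory[[1]])
  stopIfNot(!is.null(spaces) && all(nzchar(spaces)),
            "stories must be named lists of feature-space matrices")
  for (st in perStory) {
    stopIfNot(identical(names(st), spaces), "inconsistent spaces across stories")
  }
  dims <- vapply(perStory[[1]], ncol, integer(1))
  for (st in perStory) {
    stopIfNot(all(vapply(st, ncol, integer(1)) == dims),
              "inconsistent feature dims across stories")
  }
  lens <- vapply(perStory, function(st) nrow(st[[1]]), integer(1))
  for (st in perStory) {
    stopIfNot(all(vapply(st, nrow, integer(1)) == nrow(st[[1]])),
              "inconsistent TR counts across spaces within a story")
  }
  ends <- cumsum(lens)
  bounds <- cbind(start = c(1L, head(ends, -1L) + 1L), end = ends + 1L)
  delaysTr <- as.integer(delaysTr)

  newScaling <- vector("list", length(spaces))
  names(newScaling) <- spaces
  blocks <- vector("list", length(spaces) * length(delaysTr))
  maps <- vector("list", length(spaces) * length(delaysTr))
  k <- 0L
  for (sp in spaces) {
    undelayed <- do.call(rbind, lapply(perStory, `[[`, sp))
    z <- if (is.null(scaling)) {
      zscoreColumns(undelayed)
    } else {
      zscoreColumns(undelayed, center = scaling[[sp]]$center,
                    scale = scaling[[sp]]$scale)
    }
    newScaling[[sp]] <- list(center = z$center, scale = z$scale,
                             constant = z$constant)
    for (d in delaysTr) {
      k <- k + 1L
      blocks[[k]] <- delayWithinStories(z$values, bounds, d)
      maps[[k]] <- data.frame(
        space = sp, feature = seq_len(dims[[sp]]), delay = d,
        stringsAsFactors = FALSE
      )
    }
  }
  new("DesignMatrix",
    values = do.call(cbind, blocks), columnMap = do.call(rbind, maps),
    storyBounds = bounds, trS = trS, delaysTr = delaysTr,
    scaling = newScaling
  )
}

#' Restrict a design matrix to a subset of feature spaces
#'
#' Used to derive the nested (union and leave-one-out) models of the variance
#' partitioning analyses from a single full design.
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param spaces character vector of feature-space names to keep.
#' @return a \linkS4class{DesignMatrix} holding only those columns.
#' @export
subsetDesign <- function(design, spaces) {
  stopIfNot(is(design, "DesignMatrix"), "design must be a DesignMatrix")
  missing <- setdiff(spaces, unique(design@columnMap$space))
  stopIfNot(length(missing) == 0L,
            paste("unknown spaces:", paste(missing, collapse = ", ")))
  keep <- design@columnMap$space %in% spaces
  new("DesignMatrix",
    values = design@values[, keep, drop = FALSE],
    columnMap = design@columnMap[keep, , drop = FALSE],
    storyBounds = design@storyBounds, trS = design@trS,
    delaysTr = design@delaysTr, scaling = design@scaling[spaces]
  )
}

#' Encode phoneme events as binary articulatory feature vectors
#'
#' Each phoneme is mapped to an n-hot vector marking the articulations needed
#' to produce it (22 features). Phonemes absent from the table map to the
#' zero vector and are reported via a message.
#'
#' @param stream an \linkS4class{EventStream} whose labels are phoneme codes
#'   (ARPABET).
#' @param table binary matrix, phoneme x articulation; defaults to the
#'   package's shipped ARPABET table (see \code{\link{articulatoryTable}}).
#' @return an \linkS4class{EventStream} with 22-dimensional binary vectors.
#' @export
encodeArticulations <- function(stream, table = articulatoryTable()) {
  stopIfNot(is(stream, "EventStream"), "stream must be an EventStream")
  stopIfNot(all(table %in% c(0, 1)), "articulation table must be binary")
  labs <- toupper(stream@labels)
  idx <- match(labs, rownames(table))
  out <- matrix(0, nrow = length(labs), ncol = ncol(table),
                dimnames = list(NULL, colnames(table)))
  hit <- !is.na(idx)
  out[hit, ] <- table[idx[hit], , drop = FALSE]
  if (any(!hit)) {
    message(sum(!hit), " phoneme event(s) outside the articulation table ",
            "were zero-coded: ", paste(unique(labs[!hit]), collapse = ", "))
  }
  EventStream("articulatory", stream@onsets, out,
              durations = stream@durations, labels = stream@labels)
}

#' Encode part-of-speech tagged words as one-hot vectors
#'
#' @param stream an \linkS4class{EventStream} of word events.
#' @param tags character vector of POS tags, one per event; defaults to the
#'   stream labels.
#' @param inventory the fixed 17-tag inventory (see
#'   \code{\link{posInventory}}).
#' @return an \linkS4class{EventStream} with 17-dimensional one-hot vectors.
#' @export
encodePos <- function(stream, tags = stream@labels,
                      inventory = posInventory()) {
  stopIfNot(is(stream, "EventStream"), "stream must be an EventStream")
  stopIfNot(length(tags) == length(stream@onsets),
            "one tag per event required")
  idx <- match(tags, inventory)
  if (anyNA(idx)) {
    stop("POS tag(s) outside the inventory: ",
         paste(unique(tags[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  out <- matrix(0, nrow = length(tags), ncol = length(inventory),
                dimnames = list(NULL, inventory))
  out[cbind(seq_along(idx), idx)] <- 1
  EventStream("pos", stream@onsets, out,
              durations = stream@durations, labels = tags)
}

#' Look up word embeddings for word events
#'
#' In-vocabulary words receive their table row; out-of-vocabulary words
#' receive the zero vector of the table's dimensionality.
#'
#' @param stream an \linkS4class{EventStream} of word events (labels are
#'   words).
#' @param table numeric matrix, vocabulary x dim, with words as row names.
#' @param spaceName name for the resulting stream (default "semantic").
#' @return an \linkS4class{EventStream} with the table's dimensionality.
#' @export
lookupEmbeddings <- function(stream, table, spaceName = "semantic") {
  stopIfNot(is(stream, "EventStream"), "stream must be an EventStream")
  stopIfNot(!is.null(rownames(table)), "embedding table needs word row names")
  idx <- match(stream@labels, rownames(table))
  out <- matrix(0, nrow = length(stream@onsets), ncol = ncol(table))
  hit <- !is.na(idx)
  out[hit, ] <- table[idx[hit], , drop = FALSE]
  EventStream(spaceName, stream@onsets, out,
              durations = stream@durations, labels = stream@labels)
}
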
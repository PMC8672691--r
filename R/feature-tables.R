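#' Shipped articulatory feature table
#'
#' A binary table mapping the 39 ARPABET phonemes of English to 22
#' articulatory features (8 places of articulation, 6 manners, voicing, and 7
#' vowel tongue-position features). The published analyses this package
#' implements used an unenumerated 22-feature phonetic inventory; this table
#' is a synthetic stand-in with the same cardinality and the standard
#' phonetic structure, which preserves the method (any fixed binary
#' phoneme-to-articulation table of width 22 does).
#'
#' @return binary matrix, 39 phonemes x 22 articulatory features, with
#'   phoneme row names.
#' @export
articulatoryTable <- function() {
  feats <- c(
    "bilabial", "labiodental", "dental", "alveolar", "postalveolar",
    "palatal", "velar", "glottal",
    "stop", "affricate", "fricative", "nasal", "liquid", "glide",
    "voiced",
    "vowel", "front", "central", "back", "high", "mid", "low"
  )
  def <- list(
    P  = c("bilabial", "stop"),
    B  = c("bilabial", "stop", "voiced"),
    M  = c("bilabial", "nasal", "voiced"),
    W  = c("bilabial", "velar", "glide", "voiced"),
    F  = c("labiodental", "fricative"),
    V  = c("labiodental", "fricative", "voiced"),
    TH = c("dental", "fricative"),
    DH = c("dental", "fricative", "voiced"),
    T  = c("alveolar", "stop"),
    D  = c("alveolar", "stop", "voiced"),
    S  = c("alveolar", "fricative"),
    Z  = c("alveolar", "fricative", "voiced"),
    N  = c("alveolar", "nasal", "voiced"),
    L  = c("alveolar", "liquid", "voiced"),
    R  = c("alveolar", "liquid", "voiced"),
    SH = c("postalveolar", "fricative"),
    ZH = c("postalveolar", "fricative", "voiced"),
    CH = c("postalveolar", "affricate"),
    JH = c("postalveolar", "affricate", "voiced"),
    Y  = c("palatal", "glide", "voiced"),
    K  = c("velar", "stop"),
    G  = c("velar", "stop", "voiced"),
    NG = c("velar", "nasal", "voiced"),
    HH = c("glottal", "fricative"),
    IY = c("vowel", "front", "high", "voiced"),
    IH = c("vowel", "front", "high", "voiced"),
    EY = c("vowel", "front", "mid", "voiced"),
    EH = c("vowel", "front", "mid", "voiced"),
    AE = c("vowel", "front", "low", "voiced"),
    AA = c("vowel", "back", "low", "voiced"),
    AO = c("vowel", "back", "mid", "voiced"),
    OW = c("vowel", "back", "mid", "voiced"),
    UH = c("vowel", "back", "high", "voiced"),
    UW = c("vowel", "back", "high", "voiced"),
    AH = c("vowel", "central", "mid", "voiced"),
    ER = c("vowel", "central", "mid", "voiced"),
    AY = c("vowel", "central", "low", "voiced"),
    AW = c("vowel", "central", "low", "voiced"),
    OY = c("vowel", "back", "mid", "voiced")
  )
  out <- matrix(0, nrow = length(def), ncol = length(feats),
                dimnames = list(names(def), feats))
  for (ph in names(def)) out[ph, def[[ph]]] <- 1
  out
}

#' Fixed 17-tag part-of-speech inventory
#'
#' The universal part-of-speech tag set (17 categories: noun, verb, number,
#' determiner, etc.). Tags are consumed as input from an external tagger; the
#' inventory only fixes the one-hot dimensionality and ordering.
#'
#' @return character vector of 17 tags.
#' @export
posInventory <- function() {
  c("ADJ", "ADP", "ADV", "AUX", "CCONJ", "DET", "INTJ", "NOUN", "NUM",
    "PART", "PRON", "PROPN", "PUNCT", "SCONJ", "SYM", "VERB", "X")
}
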
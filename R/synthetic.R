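# Synthetic inputs for experiments and fixtures.  The generated text mimics
# the statistical shape of natural-language storage payloads (words from a
# fixed lexicon, spaces, punctuation, line breaks); the lexicon doubles as
# the reference dictionary for the text corrector.

#' Built-in lexicon used by the text generator and corrector
#' @return character vector of lowercase words
#' @export
reference_lexicon <- function() {
  c("the", "and", "a", "to", "of", "in", "was", "king", "queen", "once",
    "upon", "time", "there", "lived", "castle", "forest", "years", "child",
    "daughter", "beautiful", "spindle", "sleep", "hundred", "thorn",
    "hedge", "prince", "came", "through", "when", "she", "he", "they",
    "all", "fell", "asleep", "into", "deep", "that", "with", "her", "his",
    "had", "who", "said", "wish", "fairy", "gift", "young", "old", "tower",
    "night", "day", "every", "about", "their", "from", "this", "kingdom",
    "great", "feast", "gold", "plates", "wise", "women", "spin", "wheel",
    "finger", "prick", "curse", "wake", "kiss", "wall", "gate", "court",
    "horse", "hound", "roof", "fire", "cook", "kitchen", "maid", "roast",
    "wind", "tree", "bloom", "flower", "briar", "rose", "story", "told",
    "land", "whole", "around", "grew", "high", "could", "not", "see")
}

#' Generate pseudo-natural text
#'
#' Draws words from [reference_lexicon()] with punctuation and line breaks
#' until the requested byte length is reached (exactly; the text is
#' truncated to `n_bytes`).
#'
#' @param n_bytes target length in bytes
#' @param rng_seed seed
#' @return raw vector of ASCII text, length `n_bytes`
#' @export
synthetic_text <- function(n_bytes, rng_seed = 1) {
  lex <- reference_lexicon()
  with_local_seed(rng_seed, {
    words <- character(0)
    total <- 0
    while (total < n_bytes + 80) {
      w <- sample(lex, 1)
      r <- runif(1)
      if (r < 0.08) w <- paste0(w, ".")
      else if (r < 0.12) w <- paste0(w, ",")
      if (runif(1) < 0.07) w <- paste0(w, "\n")
      words <- c(words, w)
      total <- total + nchar(w) + 1
    }
    txt <- paste(words, collapse = " ")
    charToRaw(substr(txt, 1, n_bytes))
  })
}

#' Generate a random binary file
#' @param n_bytes length
#' @param rng_seed seed
#' @return raw vector
#' @export
random_file <- function(n_bytes, rng_seed = 1) {
  with_local_seed(rng_seed, as.raw(sample(0:255, n_bytes, replace = TRUE)))
}
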
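#' @importFrom stats median p.adjust rbinom rnorm runif t.test ks.test setNames
#' @importFrom utils read.delim write.table head
NULL

# Named substreams: every generator derives its own 32-bit seed from the root
# seed plus a stage name, so individual stages are reproducible in isolation.
substream_seed <- function(root_seed, name) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 257) %% 1000003
  as.integer((abs(as.numeric(root_seed)) * 7919 + h * 104729) %% 2147483647)
}

with_substream <- function(root_seed, name, code) {
  withr::with_seed(substream_seed(root_seed, name), code)
}

str_rev <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", str_rev(x))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Collapse isoleucine to leucine
#'
#' Isoleucine and leucine are isobaric and indistinguishable by standard
#' shotgun MS, so all sequence matching against the known proteome treats
#' them as equivalent.
#'
#' @param x character vector of amino-acid strings.
#' @return `x` with every `I` replaced by `L`.
#' @export
il_collapse <- function(x) chartr("I", "L", x)

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
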
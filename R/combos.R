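#' Construct a hypothesis combination
#'
#' @param a osteoclast-regulation variant, 1, 2 or 3: under a1 constant
#'   formation plus a pro-inflammatory contribution, inhibited by M2; under
#'   a2 the same formation inhibited by osteoblasts (OPG); under a3
#'   osteoblast-proportional formation (RANKL) inhibited by M2.
#' @param b osteoblast-expansion variant: b1 expansion driven by
#'   anti-inflammatory macrophages, b2 by injury factors.
#' @param c polarization variant: c1 injury-driven pro- and anti-inflammatory
#'   polarization; c2 pro-inflammatory-driven anti-inflammatory polarization;
#'   c3 resident-macrophage polarization with debris-uptake repolarization.
#' @return a \code{\linkS4class{HypothesisCombo}}.
#' @examples
#' hypothesisCombo(3, 2, 2)
#' comboName(hypothesisCombo(3, 2, 2))
#' @export
hypothesisCombo <- function(a, b, c) {
  new("HypothesisCombo", a = as.integer(a), b = as.integer(b),
      c = as.integer(c))
}

#' Parse a canonical combination name such as "a3b2c2"
#'
#' @param x character scalar of the form "a<i>b<j>c<k>".
#' @return a \code{\linkS4class{HypothesisCombo}}.
#' @export
parseCombo <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^a([0-9]+)b([0-9]+)c([0-9]+)$", x))[[1]]
  if (length(m) != 4L)
    stop("invalid combination name: '", x, "' (expected e.g. 'a3b2c2')")
  tryCatch(
    hypothesisCombo(as.integer(m[2]), as.integer(m[3]), as.integer(m[4])),
    error = function(e)
      stop("invalid combination name: '", x, "' (", conditionMessage(e), ")",
           call. = FALSE))
}

#' Canonical name of a hypothesis combination
#'
#' @param object a \code{HypothesisCombo}.
#' @return character, e.g. \code{"a3b2c2"}.
#' @export
setGeneric("comboName", function(object) standardGeneric("comboName"))

#' @rdname comboName
#' @export
setMethod("comboName", "HypothesisCombo", function(object) {
  sprintf("a%db%dc%d", object@a, object@b, object@c)
})

setMethod("show", "HypothesisCombo", function(object) {
  cat("HypothesisCombo", comboName(object), "\n")
})

#' Enumerate the full 18-member hypothesis space
#'
#' The Cartesian product \{a1,a2,a3\} x \{b1,b2\} x \{c1,c2,c3\} in
#' deterministic a-major order.
#'
#' @return named list of 18 \code{HypothesisCombo} objects.
#' @examples
#' length(enumerateCombos())
#' names(enumerateCombos())[1:3]
#' @export
enumerateCombos <- function() {
  combos <- list()
  for (a in 1:3) for (b in 1:2) for (c in 1:3)
    combos[[sprintf("a%db%dc%d", a, b, c)]] <- hypothesisCombo(a, b, c)
  combos
}
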
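#' DNA sequences corresponding to the let-7 microRNA family
#'
#' The four 22-base DNA analogues of the let-7 microRNA cancer marker used
#' throughout the package examples. let-7c, let-7e and let-7f each differ
#' from let-7a by a single base, at positions 19, 9 and 12 respectively
#' (A>G, T>G and G>A). None of the four contains cytosine, which is why the
#' default calling alphabet is {T, A, G}.
#'
#' @return Named character vector with elements `let7a`, `let7c`, `let7e`,
#'   `let7f`.
#' @examples
#' let7_sequences()["let7a"]
#' @export
let7_sequences <- function() {
  c(
    let7a = "TGAGGTAGTAGGTTGTATAGTT",
    let7c = "TGAGGTAGTAGGTTGTATGGTT",
    let7e = "TGAGGTAGGAGGTTGTATAGTT",
    let7f = "TGAGGTAGTAGATTGTATAGTT"
  )
}
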
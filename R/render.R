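# Serialization: CSV and JSON emitters.  JSON always carries the exact
# rational (numerator/denominator) alongside the decimal rendering so that
# no exactness is lost in a round trip; num and den are emitted as JSON
# numbers when they fit a double exactly and as decimal strings otherwise.

.bnAsJSONScalar <- function(bn) {
  v <- .bnToNum(bn)
  if (v <= 2^53) v else .bnToString(bn)
}

#' JSON-ready representation of an exact rational
#'
#' @param x a [Rational] (or numeric, converted exactly).
#' @param digits decimal places for the accompanying decimal rendering.
#' @return list with elements `num`, `den` and `decimal`.
#' @export
ratToJSON <- function(x, digits = 4) {
  r <- .ri(asRational(x))
  num <- .bnAsJSONScalar(r$n)
  if (is.numeric(num)) num <- r$s * num
  else if (r$s < 0L) num <- paste0("-", num)
  list(num = num, den = .bnAsJSONScalar(r$d), decimal = ratRound(.R(r), digits))
}

#' Reconstruct a Rational from its JSON representation
#'
#' Inverse of [ratToJSON()]: accepts the `num`/`den` pair (numbers or decimal
#' strings) and returns the exact rational; the `decimal` field is ignored.
#'
#' @param x list with elements `num` and `den`.
#' @return A [Rational].
#' @export
ratFromJSON <- function(x) {
  parse1 <- function(v) {
    if (is.numeric(v)) return(list(s = sign(v), bn = .bnFromNum(abs(v))))
    v <- as.character(v)
    s <- 1
    if (startsWith(v, "-")) { s <- -1; v <- substring(v, 2) }
    digits <- as.numeric(strsplit(v, "")[[1]])
    bn <- 0
    for (d in digits) bn <- .bnAdd(.bnMulSmall(bn, 10), .bnFromNum(d))
    list(s = s, bn = bn)
  }
  num <- parse1(x$num); den <- parse1(x$den)
  .R(.rMake(as.integer(num$s * den$s), num$bn, den$bn))
}

.writeOut <- function(text, out) {
  if (is.null(out) || identical(out, "-")) cat(text, sep = "\n")
  else writeLines(text, out)
}

# data.frame -> RFC-4180-ish CSV text
.dfToCSV <- function(df) {
  con <- textConnection("csvOut", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  csvOut
}

#' Serialize a grid or breakdown table
#'
#' @param x a data.frame (e.g. from [icTable()] or [breakdownTable()]).
#' @param format `"csv"`, `"json"` or `"text"`.
#' @return character vector of output lines (invisibly when printed).
#' @export
renderTable <- function(x, format = c("csv", "json", "text")) {
  format <- match.arg(format)
  switch(format,
    csv = .dfToCSV(x),
    json = jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE, digits = NA),
    text = utils::capture.output(print(x, row.names = FALSE)))
}
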
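## The three lookup tables driving the argument calculus ship as JSON so an
## alternative calculus can be swapped in; the packaged default is the
## reference scheme (3x3 grade weighting, 5x5 same-direction combination,
## 5x5 signed opposition).

.tableCache <- new.env(parent = emptyenv())

parseSigned <- function(s) {
  if (s == "0") return(balanced())
  dir <- if (startsWith(s, "-")) "Against" else "For"
  abbr <- sub("^-", "", s)
  lev <- c(VL = "VeryLow", L = "Low", M = "Medium", H = "High", VH = "VeryHigh")
  mag <- lev[[abbr]]
  if (is.null(mag)) stop("bad signed strength string: ", s)
  SignedStrength(mag, dir)
}

#' Load a calculus-table file
#'
#' Reads the JSON description of the three lookup tables: `weighting`
#' (reliability x convincingness -> strength), `combination` (strength x
#' strength -> strength for same-direction arguments) and `opposition`
#' (against-strength x for-strength -> signed strength). The packaged default
#' at `system.file("extdata", "calculus_tables.json", package = "aopnet")`
#' encodes the reference scheme used throughout.
#'
#' @param path Path to a JSON table file; `NULL` loads the packaged default.
#' @return A list with matrices `weighting` (dimnames reliability x
#'   convincingness), `combination` and `opposition` (dimnames strength x
#'   strength; opposition cells are signed strings such as `"-M"` or `"0"`),
#'   plus the `levels` and `grades` vectors.
#' @examples
#' tabs <- loadCalculusTables()
#' tabs$combination["VeryLow", "VeryLow"]
#' @export
loadCalculusTables <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "calculus_tables.json", package = "aopnet")
  raw <- jsonlite::read_json(path)
  lev <- unlist(raw$levels)
  grd <- unlist(raw$grades)
  asMatrix <- function(block, rows, cols) {
    m <- matrix(NA_character_, length(rows), length(cols),
                dimnames = list(rows, cols))
    for (r in rows) for (cc in cols) {
      v <- block[[r]][[cc]]
      if (is.null(v)) stop("calculus table missing cell ", r, " x ", cc)
      m[r, cc] <- v
    }
    m
  }
  gradesDesc <- rev(grd)  # tables are written Large..Small
  list(levels = lev, grades = grd,
       weighting = asMatrix(raw$weighting, gradesDesc, gradesDesc),
       combination = asMatrix(raw$combination, rev(lev), rev(lev)),
       opposition = asMatrix(raw$opposition, rev(lev), rev(lev)))
}

#' @rdname loadCalculusTables
#' @export
defaultCalculusTables <- function() {
  if (is.null(.tableCache$default))
    .tableCache$default <- loadCalculusTables()
  .tableCache$default
}

checkTables <- function(tables) {
  if (is.null(tables) || length(tables) == 0L) defaultCalculusTables()
  else tables
}
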
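.dyadqc <- new.env(parent = emptyenv())

#' The eight-dyad emotion category system
#'
#' Loads (and caches) the fixed category system used throughout the package:
#' the eight Plutchik emotion dyads, their positions on the Plutchik wheel,
#' and the mapping of the 26 EMOTIC emotion words into the dyads. Dyad ids
#' 1--8 are the I/O identifiers (alphabetical by leading emotion); wheel
#' positions 0--7 encode the circular geometry, with antagonistic emotions
#' (joy/sadness, trust/disgust, fear/anger, surprise/anticipation) placed
#' four steps -- 180 degrees -- apart.
#'
#' @return An object of class `dyad_catalog`: a list with
#'   \describe{
#'     \item{dyads}{data.frame with columns `id`, `name_pair`,
#'       `wheel_position`, one row per dyad, ordered by id.}
#'     \item{emotic_map}{named integer vector mapping each of the 26 EMOTIC
#'       emotion words (lower-cased) to a dyad id.}
#'   }
#' @export
#' @examples
#' cat <- dyad_catalog()
#' cat$dyads
dyad_catalog <- function() {
  if (!is.null(.dyadqc$catalog)) {
    return(.dyadqc$catalog)
  }
  path <- system.file("extdata", "dyad_catalog.json", package = "dyadqc")
  if (!nzchar(path)) {
    stop("dyad catalog resource not found; is the package installed?")
  }
  raw <- jsonlite::fromJSON(path)
  dyads <- data.frame(
    id = as.integer(raw$dyads$id),
    name_pair = as.character(raw$dyads$name_pair),
    wheel_position = as.integer(raw$dyads$wheel_position),
    stringsAsFactors = FALSE
  )
  emotic_map <- vapply(raw$emotic_map, as.integer, integer(1))
  names(emotic_map) <- tolower(names(raw$emotic_map))

  stopifnot(
    identical(sort(dyads$id), 1:8),
    identical(sort(dyads$wheel_position), 0:7),
    length(emotic_map) == 26L,
    all(emotic_map %in% 1:8)
  )
  dyads <- dyads[order(dyads$id), , drop = FALSE]
  rownames(dyads) <- NULL

  catalog <- structure(
    list(dyads = dyads, emotic_map = emotic_map),
    class = "dyad_catalog"
  )
  # opposite must be an involution with no fixed point
  opp <- opposite_dyad(1:8, catalog)
  stopifnot(all(opposite_dyad(opp, catalog) == 1:8), all(opp != 1:8))
  .dyadqc$catalog <- catalog
  catalog
}

#' @export
print.dyad_catalog <- function(x, ...) {
  cat("Plutchik dyad catalog: 8 dyads, 26 EMOTIC words\n")
  print(x$dyads, row.names = FALSE)
  invisible(x)
}

#' Map EMOTIC emotion words to dyad ids
#'
#' Matches each word against the 26-word EMOTIC vocabulary
#' (case-insensitive, surrounding whitespace ignored; the vocabulary keeps
#' the spellings of the source annotations, e.g. `"Doubt/Confussion"`) and
#' returns the id of the Plutchik dyad housing it.
#'
#' @param word character vector of EMOTIC emotion words.
#' @param catalog a [dyad_catalog()].
#' @return integer vector of dyad ids (1--8), same length as `word`.
#' @export
#' @examples
#' map_emotic_label(c("Annoyance", "Engagement", "anger"))
map_emotic_label <- function(word, catalog = dyad_catalog()) {
  w <- tolower(trimws(as.character(word)))
  idx <- match(w, names(catalog$emotic_map))
  if (anyNA(idx)) {
    bad <- unique(word[is.na(idx)])
    stop("unknown EMOTIC emotion word(s): ", paste(sQuote(bad), collapse = ", "))
  }
  unname(catalog$emotic_map[idx])
}

.check_dyad_id <- function(id) {
  if (!all(id %in% 1:8)) {
    stop("invalid dyad id(s): ", paste(unique(id[!id %in% 1:8]), collapse = ", "),
         " (must be integers 1-8)")
  }
  as.integer(id)
}

#' Circular distance between two dyads on the Plutchik wheel
#'
#' The minimal number of steps between the wheel positions of two dyads,
#' an integer 0--4; distance 4 identifies the antagonistic (opposite) pair.
#'
#' @param a,b dyad ids (vectors are recycled to a common length).
#' @param catalog a [dyad_catalog()].
#' @return integer vector of distances in 0--4.
#' @export
#' @examples
#' wheel_distance(5, 6) # joy vs sadness: opposites
wheel_distance <- function(a, b, catalog = dyad_catalog()) {
  a <- .check_dyad_id(a)
  b <- .check_dyad_id(b)
  pos <- catalog$dyads$wheel_position[order(catalog$dyads$id)]
  d <- abs(pos[a] - pos[b])
  as.integer(pmin(d, 8L - d))
}

#' Antagonistic dyad on the Plutchik wheel
#'
#' @param a dyad id vector.
#' @param catalog a [dyad_catalog()].
#' @return integer vector: the dyad sitting 180 degrees opposite each `a`.
#' @export
opposite_dyad <- function(a, catalog = dyad_catalog()) {
  a <- .check_dyad_id(a)
  pos <- catalog$dyads$wheel_position[order(catalog$dyads$id)]
  target <- (pos[a] + 4L) %% 8L
  # invert position -> id
  id_at_pos <- integer(8)
  id_at_pos[pos + 1L] <- catalog$dyads$id
  id_at_pos[target + 1L]
}

#' Dyad display names
#'
#' @param id dyad id vector.
#' @param catalog a [dyad_catalog()].
#' @return character vector of `name_pair` strings, e.g. `"Joy/Affection"`.
#' @export
dyad_name <- function(id, catalog = dyad_catalog()) {
  id <- .check_dyad_id(id)
  catalog$dyads$name_pair[id]
}
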
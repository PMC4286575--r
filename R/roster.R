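#' Build a family roster
#'
#' A roster lists the conscripted male members of one family; twins are
#' marked by a shared `twin_set_id`.
#'
#' @param family_id Opaque family identifier.
#' @param person_id Character or integer member ids.
#' @param birth_year Integer birth years, one per member.
#' @param twin_set_id Optional twin-set labels (`NA` for non-twins); each
#'   non-`NA` label must be shared by exactly two members.
#' @return A `family_roster` list.
#' @export
family_roster <- function(family_id, person_id, birth_year, twin_set_id = NULL) {
  n <- length(person_id)
  if (is.null(twin_set_id)) twin_set_id <- rep(NA_character_, n)
  stopifnot(length(birth_year) == n, length(twin_set_id) == n)
  sets <- table(twin_set_id[!is.na(twin_set_id)])
  if (any(sets != 2L)) {
    stop("each twin_set_id must be shared by exactly two members", call. = FALSE)
  }
  structure(
    list(family_id = family_id,
         members = data.frame(person_id = person_id,
                              birth_year = as.integer(birth_year),
                              twin_set_id = twin_set_id,
                              stringsAsFactors = FALSE)),
    class = "family_roster"
  )
}

#' Select the study pair from a family
#'
#' Implements the one-pair-per-family sampling rule: take the twin pair if
#' the family contains one (the youngest pair if it contains several); with
#' no twins, take the two brothers closest in age, breaking ties on equal
#' age gap in favour of the youngest pair.
#'
#' @param roster A [family_roster()].
#' @return Character vector of the two selected `person_id`s, ordered by
#'   birth year.
#' @export
#' @examples
#' r <- family_roster("f1", c("a", "b", "c"), c(1984, 1986, 1991))
#' select_study_pair(r)  # the 1984/1986 brothers: smallest age gap
select_study_pair <- function(roster) {
  stopifnot(inherits(roster, "family_roster"))
  m <- roster$members
  if (nrow(m) < 2L) {
    stop("family has fewer than two members: no pair to select", call. = FALSE)
  }
  twin_sets <- unique(m$twin_set_id[!is.na(m$twin_set_id)])
  if (length(twin_sets)) {
    yrs <- vapply(twin_sets, function(s) m$birth_year[m$twin_set_id %in% s][1], 0L)
    pick <- twin_sets[which.max(yrs)]           # youngest twin pair
    sel <- m[m$twin_set_id %in% pick, ]
  } else {
    m <- m[order(m$birth_year), ]
    gaps <- diff(m$birth_year)                  # adjacent-in-age candidates
    best <- min(gaps)
    i <- max(which(gaps == best))               # youngest among equal gaps
    sel <- m[c(i, i + 1L), ]
  }
  sel$person_id[order(sel$birth_year)]
}
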
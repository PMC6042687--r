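# Three-band-probe fold configurations. Three probes tile one chromosome
# arm near its centromere (cen), middle (mid) and telomere (tel); the 3-bit
# contact pattern among them defines 8 fold states, and the arm is "closed"
# iff the cen and tel probes touch, regardless of the other two contacts.

#' Classify the fold configuration of one chromosome arm
#'
#' Evaluates the three pairwise contacts (cen-mid, mid-tel, cen-tel) with
#' [in_contact()] and encodes them as a state id 0-7 (cen-tel is the high
#' bit, then mid-tel, then cen-mid). `closed` is `TRUE` iff cen-tel are in
#' contact. Probes that segment into several components are used as their
#' union (each probe is one domain).
#'
#' @param cen_mask,mid_mask,tel_mask non-empty 3D logical arrays on one
#'   grid (an empty/missing probe yields an unclassifiable `NA` state,
#'   never a silent "open").
#' @param contact_mode passed to [in_contact()].
#' @return list of class `ct_configuration`: `contacts` (named logical:
#'   cen_mid, mid_tel, cen_tel), `state_id` (0-7 or `NA`), `closed`.
#' @export
classify_configuration <- function(cen_mask, mid_mask, tel_mask,
                                   contact_mode = c("adjacency", "intersection")) {
  contact_mode <- match.arg(contact_mode)
  missing_probe <- is.null(cen_mask) || is.null(mid_mask) || is.null(tel_mask) ||
    !any(cen_mask) || !any(mid_mask) || !any(tel_mask)
  if (missing_probe) {
    return(structure(list(contacts = c(cen_mid = NA, mid_tel = NA, cen_tel = NA),
                          state_id = NA_integer_, closed = NA),
                     class = "ct_configuration"))
  }
  contacts <- c(
    cen_mid = in_contact(cen_mask, mid_mask, contact_mode),
    mid_tel = in_contact(mid_mask, tel_mask, contact_mode),
    cen_tel = in_contact(cen_mask, tel_mask, contact_mode)
  )
  structure(
    list(contacts = contacts,
         state_id = configuration_state_id(contacts),
         closed = unname(contacts["cen_tel"])),
    class = "ct_configuration"
  )
}

#' @rdname classify_configuration
#' @param contacts named logical vector `(cen_mid, mid_tel, cen_tel)`.
#' @export
configuration_state_id <- function(contacts) {
  as.integer(4L * contacts[["cen_tel"]] + 2L * contacts[["mid_tel"]] +
               1L * contacts[["cen_mid"]])
}

#' @export
print.ct_configuration <- function(x, ...) {
  cat(sprintf("<ct_configuration> state %s (%s)\n",
              x$state_id, if (isTRUE(x$closed)) "closed"
              else if (isFALSE(x$closed)) "open" else "unclassifiable"))
  invisible(x)
}

#' Population frequencies of the eight fold configurations
#'
#' @param states integer vector of state ids 0-7 (`NA` dropped with a
#'   count), or a list of [classify_configuration()] results.
#' @return list: `frequencies` (tibble: state, closed, n, fraction),
#'   `open_fraction`, `closed_fraction`, `n`, `n_missing`. Closed states are
#'   exactly those with the cen-tel bit set (4, 5, 6, 7).
#' @export
configuration_frequencies <- function(states) {
  if (is.list(states)) {
    states <- vapply(states, function(s) {
      if (inherits(s, "ct_configuration")) s$state_id else as.integer(s)
    }, 1L)
  }
  n_missing <- sum(is.na(states))
  states <- states[!is.na(states)]
  if (length(states) == 0L) stop("no classified cells", call. = FALSE)
  if (any(states < 0L | states > 7L)) stop("state ids must be 0-7", call. = FALSE)
  counts <- tabulate(states + 1L, nbins = 8L)
  freq <- tibble::tibble(
    state = 0:7,
    closed = bitwAnd(0:7, 4L) > 0L,
    n = counts,
    fraction = counts / length(states)
  )
  list(frequencies = freq,
       open_fraction = sum(freq$fraction[!freq$closed]),
       closed_fraction = sum(freq$fraction[freq$closed]),
       n = length(states), n_missing = n_missing)
}
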
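#' Multi-implant planning session
#'
#' A session holds the implants of one planning case: a list of immutable
#' saved implants plus at most one current (still adjustable) implant.
#' Typical use: assemble, [set_current()], [save_current()], repeat for the
#' next plate, then [export_session()] - fracture treatment often needs more
#' than one miniplate.
#'
#' @return an empty `planning_session`.
#' @export
planning_session <- function() {
  structure(list(saved = list(), current = NULL), class = "planning_session")
}

#' @export
print.planning_session <- function(x, ...) {
  cat(sprintf("<planning_session> %d saved implant(s), current: %s\n",
              length(x$saved),
              if (is.null(x$current)) "none" else x$current$spec_id))
  invisible(x)
}

#' Set the current implant of a session
#' @param session a [planning_session()].
#' @param implant an `implant_model` (see [assemble_implant()]).
#' @return the updated session.
#' @export
set_current <- function(session, implant) {
  stopifnot(inherits(session, "planning_session"), inherits(implant, "implant_model"))
  session$current <- implant
  session
}

#' Save the current implant
#'
#' Appends the current implant to the saved list and clears the current slot;
#' saved implants are never mutated afterwards.
#'
#' @param session a [planning_session()] with a current implant.
#' @return the updated session.
#' @export
save_current <- function(session) {
  stopifnot(inherits(session, "planning_session"))
  if (is.null(session$current)) {
    stop("no current implant to save", call. = FALSE)
  }
  session$saved <- c(session$saved, list(session$current))
  session$current <- NULL
  session
}

#' Export all implants of a session to one STL file
#'
#' Writes the merged meshes of all saved implants plus the current one (if
#' present, saved or not) as a single STL.
#'
#' @param session a [planning_session()] with at least one implant.
#' @param path output STL path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
export_session <- function(session, path, dialect = "binary") {
  stopifnot(inherits(session, "planning_session"))
  implants <- session$saved
  if (!is.null(session$current)) implants <- c(implants, list(session$current))
  if (length(implants) == 0L) {
    stop("empty session: nothing to export", call. = FALSE)
  }
  write_stl(merge_meshes(lapply(implants, `[[`, "mesh")), path, dialect)
}
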
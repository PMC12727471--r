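#' Metabolite spin-system library
#'
#' Spin-system parameters are shipped as a JSON asset (see
#' `inst/extdata/metabolite_library.json`) with one entry per species:
#' `{name, source_id, population, spins: [{shift_ppm, multiplicity}],
#' couplings: [[Hz]]}`. Couplings are given on the unexpanded spins; a spin
#' with multiplicity m is expanded into m magnetically equivalent copies, each
#' inheriting the couplings of the base spin (intra-group couplings are set to
#' zero — couplings between magnetically equivalent nuclei do not affect the
#' spectrum).
#'
#' @name metabolite-library
NULL

#' Load a metabolite spin-system library
#'
#' @param path Path to a library JSON file; defaults to the bundled asset.
#' @return Object of class `metabolite_library`: a named list of
#'   [spin_system()] objects plus alias metadata (`glucose` resolves to the
#'   alpha/beta anomer pair with populations 0.36/0.64).
#' @export
load_metabolite_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "metabolite_library.json", package = "lfnmr")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$species)) stop("library JSON is missing the 'species' field")
  systems <- list()
  for (entry in raw$species) {
    for (f in c("name", "spins", "couplings")) {
      if (is.null(entry[[f]])) {
        stop(sprintf("library entry is missing required field '%s'", f))
      }
    }
    shifts <- vapply(entry$spins, function(s) {
      if (is.null(s$shift_ppm)) stop("spin entry is missing field 'shift_ppm'")
      as.numeric(s$shift_ppm)
    }, numeric(1))
    mult <- vapply(entry$spins, function(s) {
      m <- if (is.null(s$multiplicity)) 1L else as.integer(s$multiplicity)
      if (m < 1L) stop("multiplicity must be >= 1")
      m
    }, integer(1))
    J <- do.call(rbind, lapply(entry$couplings, function(r) as.numeric(unlist(r))))
    if (any(abs(J - t(J)) > 1e-12)) {
      stop(sprintf("species '%s': couplings matrix must be symmetric", entry$name))
    }
    # expand multiplicities into explicit equivalent spins
    group <- rep(seq_along(shifts), mult)
    ex_shifts <- shifts[group]
    nex <- length(ex_shifts)
    exJ <- matrix(0, nex, nex)
    for (a in seq_len(nex)) for (b in seq_len(nex)) {
      if (group[a] != group[b]) exJ[a, b] <- J[group[a], group[b]]
    }
    pop <- if (is.null(entry$population)) 1 else as.numeric(entry$population)
    systems[[entry$name]] <- spin_system(entry$name, ex_shifts, exJ, pop)
    attr(systems[[entry$name]], "source_id") <- entry$source_id
  }
  structure(list(systems = systems,
                 aliases = list(glucose = c("glucose_alpha", "glucose_beta"))),
            class = "metabolite_library")
}

# Bundled library, loaded once per session.
.library_cache <- new.env(parent = emptyenv())

#' The bundled metabolite library
#' @return A `metabolite_library` with glucose (alpha/beta anomers), lactate,
#'   citrate and TSP.
#' @export
default_library <- function() {
  if (is.null(.library_cache$lib)) {
    .library_cache$lib <- load_metabolite_library()
  }
  .library_cache$lib
}

#' Resolve a species name to its spin system(s)
#'
#' @param library A `metabolite_library`.
#' @param name Species name; aliases (e.g. `glucose`) expand to several
#'   systems whose populations weight their contributions.
#' @return List of `spin_system` objects.
#' @export
resolve_species <- function(library, name) {
  stopifnot(inherits(library, "metabolite_library"))
  if (!is.null(library$aliases[[name]])) {
    return(unname(library$systems[library$aliases[[name]]]))
  }
  if (!is.null(library$systems[[name]])) return(list(library$systems[[name]]))
  stop(sprintf("unknown species '%s'; available: %s", name,
               paste(c(names(library$aliases), names(library$systems)),
                     collapse = ", ")))
}

#' @export
print.metabolite_library <- function(x, ...) {
  cat("<metabolite_library>\n")
  for (nm in names(x$systems)) {
    s <- x$systems[[nm]]
    cat(sprintf("  %-14s %d spin(s), population %.2f\n",
                nm, length(s$shifts), s$population))
  }
  invisible(x)
}
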
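# Regulatory schemes: lists of regulator -> enzyme edges with a mode.
#
# The regulating species "ceramide" is resolved to the pooled free-ceramide
# concentration; every other regulator must be a metabolite or regulator
# species of the network. The baseline ORM -| SPT inhibition is present in
# every scheme handled by the screening pipeline.

.BASELINE_EDGE <- data.frame(regulator = "orm", target = "SPT", mode = "inhibition",
                             stringsAsFactors = FALSE)

#' Create a regulatory scheme
#'
#' @param edges data frame with columns `regulator`, `target`, `mode`
#'   (`"activation"` or `"inhibition"`). The `regulator` value `"ceramide"`
#'   denotes the pooled free-ceramide signal.
#' @param scheme_id identifier string.
#' @param add_baseline prepend the ORM -| SPT edge if absent (default `TRUE`).
#' @return a `sphingo_scheme`
#' @export
new_scheme <- function(edges, scheme_id = "scheme", add_baseline = TRUE) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- .BASELINE_EDGE[0, ]
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("regulator", "target", "mode")
  if (!all(need %in% names(edges))) {
    sphingo_abort("scheme", "scheme edges need columns regulator, target, mode")
  }
  edges <- edges[, need]
  if (add_baseline &&
      !any(edges$regulator == "orm" & edges$target == "SPT")) {
    edges <- rbind(.BASELINE_EDGE, edges)
  }
  bad_mode <- setdiff(edges$mode, c("activation", "inhibition"))
  if (length(bad_mode)) {
    sphingo_abort("scheme", "unknown regulation mode: ", paste(bad_mode, collapse = ", "))
  }
  key <- paste(edges$regulator, edges$target)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    modes <- vapply(dups, function(k) length(unique(edges$mode[key == k])), integer(1))
    if (any(modes > 1L)) {
      sphingo_abort("scheme", "contradictory duplicate edge (both modes) for: ",
                    paste(dups[modes > 1L], collapse = ", "))
    }
    edges <- edges[!duplicated(key), ]
  }
  rownames(edges) <- NULL
  structure(list(scheme_id = scheme_id, edges = edges), class = "sphingo_scheme")
}

#' Validate a scheme against a network
#'
#' Checks that every regulator resolves to a species (or the ceramide pool)
#' and every target to an enzyme with at least one enzymatic reaction.
#' @param scheme `sphingo_scheme`
#' @param net `sphingo_network`
#' @return scheme, invisibly
#' @export
validate_scheme <- function(scheme, net) {
  stopifnot(inherits(scheme, "sphingo_scheme"))
  enzymes <- unique(net$reactions$enzyme[net$reactions$type == "enzymatic"])
  regulators <- net$metabolites$id[net$metabolites$species_class == "regulator"]
  for (i in seq_len(nrow(scheme$edges))) {
    e <- scheme$edges[i, ]
    if (!(e$target %in% enzymes) && !(e$target %in% regulators)) {
      sphingo_abort("scheme", "edge targets unknown enzyme '", e$target, "'")
    }
    if (e$target %in% regulators && e$mode != "inhibition") {
      sphingo_abort("scheme", "regulator-targeting edges must be inhibitory (sequestration)")
    }
    if (e$regulator != "ceramide" && !(e$regulator %in% net$metabolites$id)) {
      sphingo_abort("scheme", "unknown regulator species '", e$regulator, "'")
    }
    if (e$regulator == "ceramide" && length(free_ceramide_species(net)) == 0L) {
      sphingo_abort("scheme", "network has no free ceramide species to form the pool")
    }
  }
  invisible(scheme)
}

#' Load schemes from a TSV file
#'
#' Expects columns `scheme_id`, `regulator`, `target`, `mode`; one row per
#' edge, multiple rows per scheme.
#' @param path TSV path
#' @param add_baseline add ORM -| SPT to every scheme if absent
#' @return list of `sphingo_scheme`
#' @export
load_schemes <- function(path, add_baseline = TRUE) {
  if (!file.exists(path)) sphingo_abort("io", "scheme file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("scheme_id", "regulator", "target", "mode")
  if (!all(need %in% names(tab))) {
    sphingo_abort("format", "scheme file needs columns ", paste(need, collapse = ", "))
  }
  ids <- unique(tab$scheme_id)
  lapply(ids, function(id) {
    new_scheme(tab[tab$scheme_id == id, c("regulator", "target", "mode")],
               scheme_id = id, add_baseline = add_baseline)
  })
}

#' Enumerate regulatory schemes from a candidate edge list
#'
#' Builds all combinations of the candidate edges: for each (regulator,
#' target) pair the options are "absent" plus each mode listed for that pair;
#' the empty combination is the baseline-only scheme. When `override` (a
#' scheme TSV path or a list of schemes) is supplied it replaces enumeration,
#' which is how a curated scheme list takes precedence over the combinatorial
#' reconstruction.
#'
#' @param candidates data frame with columns `regulator`, `target`, `mode`;
#'   the same pair may appear with both modes (treated as alternatives).
#' @param override optional scheme TSV path or list of `sphingo_scheme`.
#' @param include_empty include the baseline-only scheme (default `TRUE`).
#' @return list of `sphingo_scheme`
#' @export
enumerate_schemes <- function(candidates = NULL, override = NULL, include_empty = TRUE) {
  if (!is.null(override)) {
    if (is.character(override)) return(load_schemes(override))
    return(override)
  }
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(list(new_scheme(NULL, scheme_id = "baseline")))
  }
  key <- paste(candidates$regulator, candidates$target, sep = "|")
  pairs <- unique(key)
  options <- lapply(pairs, function(k) c(NA_character_, unique(candidates$mode[key == k])))
  grid <- expand.grid(options, stringsAsFactors = FALSE)
  schemes <- list()
  n <- 0L
  for (r in seq_len(nrow(grid))) {
    sel <- !is.na(unlist(grid[r, ]))
    if (!any(sel) && !include_empty) next
    edges <- data.frame(
      regulator = sub("\\|.*", "", pairs[sel]),
      target = sub(".*\\|", "", pairs[sel]),
      mode = unlist(grid[r, sel], use.names = FALSE),
      stringsAsFactors = FALSE
    )
    n <- n + 1L
    schemes[[n]] <- new_scheme(edges, scheme_id = sprintf("scheme%02d", n))
  }
  # deduplicate on canonical edge signature
  sig <- vapply(schemes, function(s) {
    e <- s$edges[order(s$edges$regulator, s$edges$target), ]
    paste(e$regulator, e$target, e$mode, collapse = ";")
  }, character(1))
  schemes[!duplicated(sig)]
}

#' @export
print.sphingo_scheme <- function(x, ...) {
  cat("<sphingo_scheme> ", x$scheme_id, "\n", sep = "")
  sym <- ifelse(x$edges$mode == "activation", " -> ", " -| ")
  cat(paste0("  ", x$edges$regulator, sym, x$edges$target, collapse = "\n"), "\n")
  invisible(x)
}
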
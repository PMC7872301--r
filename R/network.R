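# Metabolic network container: loading, validation, stoichiometry.
#
# The on-disk dialect is a plain TSV with one row per reaction:
#   rxn_id  enzyme  genes  equation  delta_g0_kJ_mol  lb  ub
# where `equation` is a human-readable string such as
#   "1 serine + 1 palmitoyl_coa -> 1 ketosphinganine".
# An optional companion metabolite TSV (id, name, species_class, acyl_length,
# hydroxylation, is_buffered) overrides the built-in classification rules.

.SPECIES_CLASSES <- c("LCB", "ceramide", "hydroxyceramide", "GlcCer", "GIPC",
                      "acyl-CoA", "cofactor", "regulator", "boundary", "other")

.BUFFERED_COFACTORS <- c("serine", "nadph", "nadp", "udp_glucose", "atp", "adp",
                         "inositol_p", "glucose", "h2o", "co2")

#' Classify a metabolite id using naming conventions
#'
#' Used when no metabolite table is supplied. Acyl-CoA pools, NADPH,
#' UDP-glucose and serine are buffered (held at their reference concentration)
#' because they participate in many reactions outside the pathway and are
#' folded into the enzyme complex during elementary decomposition.
#' @noRd
classify_metabolite <- function(id) {
  lid <- tolower(id)
  if (grepl("coa$", lid)) return(list(class = "acyl-CoA", buffered = TRUE))
  if (lid %in% .BUFFERED_COFACTORS) return(list(class = "cofactor", buffered = TRUE))
  if (grepl("^orm", lid)) return(list(class = "regulator", buffered = FALSE))
  if (grepl("^gipc", lid)) return(list(class = "GIPC", buffered = FALSE))
  if (grepl("^glccer", lid)) return(list(class = "GlcCer", buffered = FALSE))
  if (grepl("^cer", lid)) {
    hydrox <- grepl("_h?c[0-9]+", lid) && grepl("_hc[0-9]+", lid)
    return(list(class = if (hydrox) "hydroxyceramide" else "ceramide", buffered = FALSE))
  }
  if (grepl("^[dt]18_", lid) || grepl("sphinganine", lid) || grepl("^ks$|ketosphinganine", lid)) {
    return(list(class = "LCB", buffered = FALSE))
  }
  list(class = "other", buffered = FALSE)
}

#' Parse one side of a reaction equation
#' @noRd
parse_equation_side <- function(side, rxn_id) {
  side <- trimws(side)
  if (side == "") return(numeric(0))
  terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
  out <- numeric(0)
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]+)?\\s*([A-Za-z][A-Za-z0-9_:\\-]*)$", tm))[[1]]
    if (length(m) == 0L) {
      sphingo_abort("format", "unparseable equation term '", tm, "' in reaction '", rxn_id, "'")
    }
    coef <- if (m[2] == "") 1 else as.numeric(m[2])
    id <- m[3]
    if (id %in% names(out)) out[[id]] <- out[[id]] + coef else out[[id]] <- coef
  }
  out
}

#' Parse a full equation string into a signed stoichiometry vector
#' @noRd
parse_equation <- function(eq, rxn_id) {
  if (is.na(eq) || !nzchar(trimws(eq))) {
    sphingo_abort("format", "empty equation in reaction '", rxn_id, "'")
  }
  m <- regexpr("<->|<=>|->|=>", eq)
  if (m[1] < 0 || length(gregexpr("<->|<=>|->|=>", eq)[[1]]) != 1L) {
    sphingo_abort("format", "equation of reaction '", rxn_id,
                  "' must contain exactly one '->': '", eq, "'")
  }
  lhs <- parse_equation_side(substr(eq, 1L, m[1] - 1L), rxn_id)
  rhs <- parse_equation_side(substr(eq, m[1] + attr(m, "match.length"), nchar(eq)), rxn_id)
  st <- c(-lhs, rhs)
  # merge species appearing on both sides
  tapply_ids <- unique(names(st))
  vapply(tapply_ids, function(id) sum(st[names(st) == id]), numeric(1))
}

#' Pool acyl-chain lengths to C16 / C24
#'
#' Acyl chain tokens shorter than 20 carbons are pooled to C16, those with 20
#' or more to C24, mirroring the dominance of C16 and C24 fatty acids in plant
#' sphingolipids. Applied to metabolite ids wherever a `c<NN>` / `hc<NN>` /
#' `c<NN>_coa` token appears.
#'
#' @param id character vector of metabolite ids
#' @return character vector with pooled ids
#' @export
pool_acyl_id <- function(id) {
  pool_one <- function(x) {
    toks <- strsplit(x, "_", fixed = TRUE)[[1]]
    m <- regmatches(toks, regexec("^(h?)c([0-9]{2})$", toks))
    for (k in seq_along(toks)) {
      if (length(m[[k]])) {
        n <- as.integer(m[[k]][3])
        toks[k] <- paste0(m[[k]][2], "c", if (n < 20L) "16" else "24")
      }
    }
    paste(toks, collapse = "_")
  }
  vapply(id, pool_one, character(1), USE.NAMES = FALSE)
}

#' Load a metabolic network from a reaction TSV
#'
#' @param path path to a reaction TSV with columns `rxn_id`, `enzyme`, `genes`,
#'   `equation`, `delta_g0_kJ_mol`, `lb`, `ub`.
#' @param metabolites_path optional metabolite TSV (columns `id`, `name`,
#'   `species_class`, `acyl_length`, `hydroxylation`, `is_buffered`) overriding
#'   the naming-convention classifier.
#' @param pool_acyl pool acyl-chain lengths to C16/C24 (default `TRUE`).
#' @return a validated `sphingo_network` object.
#' @export
load_network <- function(path, metabolites_path = NULL, pool_acyl = TRUE) {
  if (!file.exists(path)) sphingo_abort("io", "network file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("rxn_id", "enzyme", "genes", "equation", "delta_g0_kJ_mol", "lb", "ub")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    sphingo_abort("format", "network file lacks columns: ",
                  paste(missing_cols, collapse = ", "))
  }
  met_tab <- NULL
  if (!is.null(metabolites_path)) {
    met_tab <- utils::read.delim(metabolites_path, stringsAsFactors = FALSE,
                                 comment.char = "#")
  }
  build_network(tab, met_tab, pool_acyl = pool_acyl)
}

#' Construct a network from in-memory tables
#'
#' Same contract as [load_network()] but takes data frames; used by the
#' synthetic-data module so fixtures never touch disk unless asked to.
#'
#' @param reactions reaction table (see [load_network()]).
#' @param metabolites optional metabolite table.
#' @param pool_acyl pool acyl-chain lengths to C16/C24.
#' @return `sphingo_network`
#' @export
build_network <- function(reactions, metabolites = NULL, pool_acyl = TRUE) {
  tab <- reactions
  if (nrow(tab) == 0L) sphingo_abort("validation", "network has no reactions")
  if (anyDuplicated(tab$rxn_id)) {
    sphingo_abort("validation", "duplicate reaction ids: ",
                  paste(unique(tab$rxn_id[duplicated(tab$rxn_id)]), collapse = ", "))
  }
  stoich <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    st <- parse_equation(tab$equation[i], tab$rxn_id[i])
    if (pool_acyl) {
      names(st) <- pool_acyl_id(names(st))
      if (anyDuplicated(names(st))) {
        ids <- unique(names(st))
        st <- vapply(ids, function(id) sum(st[names(st) == id]), numeric(1))
      }
    }
    st <- st[st != 0]
    if (length(st) == 0L) {
      sphingo_abort("validation", "reaction '", tab$rxn_id[i],
                    "' has empty stoichiometry after pooling")
    }
    stoich[[i]] <- st
  }
  type <- ifelse(tab$enzyme == "exchange", "exchange",
          ifelse(tab$enzyme == "biomass", "biomass", "enzymatic"))
  if (sum(type == "biomass") > 1L) {
    sphingo_abort("validation", "network declares more than one biomass reaction")
  }
  dg <- suppressWarnings(as.numeric(tab$delta_g0_kJ_mol))
  no_dg <- which(type == "enzymatic" & !is.finite(dg))
  if (length(no_dg)) {
    sphingo_abort("validation", "missing delta_g0 for enzymatic reaction(s): ",
                  paste(tab$rxn_id[no_dg], collapse = ", "))
  }

  met_ids <- unique(unlist(lapply(stoich, names)))
  met <- data.frame(id = met_ids, name = met_ids, species_class = NA_character_,
                    acyl_length = NA_integer_, hydroxylation = NA_character_,
                    is_buffered = NA, stringsAsFactors = FALSE)
  if (!is.null(metabolites)) {
    if (pool_acyl) metabolites$id <- pool_acyl_id(metabolites$id)
    metabolites <- metabolites[!duplicated(metabolites$id), , drop = FALSE]
    extra <- setdiff(metabolites$id, met_ids)
    reg_extra <- metabolites$id[metabolites$id %in% extra &
                                  metabolites$species_class %in% c("regulator", "boundary")]
    bad_extra <- setdiff(extra, reg_extra)
    if (length(bad_extra)) {
      sphingo_abort("validation", "metabolite(s) declared but used in no reaction: ",
                    paste(bad_extra, collapse = ", "))
    }
    met <- merge(met, metabolites, by = "id", all.x = TRUE, suffixes = c(".infer", ""))
    keep <- c("id", "name", "species_class", "acyl_length", "hydroxylation", "is_buffered")
    met <- met[, intersect(keep, names(met)), drop = FALSE]
    if (length(reg_extra)) {
      met <- rbind(met, metabolites[metabolites$id %in% reg_extra, keep])
    }
  }
  for (i in seq_len(nrow(met))) {
    if (is.na(met$species_class[i]) || is.na(met$is_buffered[i])) {
      cl <- classify_metabolite(met$id[i])
      if (is.na(met$species_class[i])) met$species_class[i] <- cl$class
      if (is.na(met$is_buffered[i])) met$is_buffered[i] <- cl$buffered
    }
    if (is.na(met$acyl_length[i])) {
      m <- regmatches(met$id[i], regexec("_h?c([0-9]{2})(_|$)", met$id[i]))[[1]]
      met$acyl_length[i] <- if (length(m)) as.integer(m[2]) else NA_integer_
    }
  }
  bad_class <- setdiff(met$species_class, .SPECIES_CLASSES)
  if (length(bad_class)) {
    sphingo_abort("validation", "unknown species_class: ", paste(bad_class, collapse = ", "))
  }
  # palmitoyl-CoA and cofactors must be buffered
  must_buffer <- met$species_class %in% c("acyl-CoA", "cofactor")
  if (any(must_buffer & !met$is_buffered)) {
    sphingo_abort("validation", "cofactor/acyl-CoA species must be buffered: ",
                  paste(met$id[must_buffer & !met$is_buffered], collapse = ", "))
  }

  rxn <- data.frame(
    id = tab$rxn_id, enzyme = tab$enzyme,
    genes = as.character(tab$genes),
    delta_g0 = dg,
    lb = suppressWarnings(as.numeric(tab$lb)),
    ub = suppressWarnings(as.numeric(tab$ub)),
    type = type,
    stringsAsFactors = FALSE
  )
  rxn$lb[is.na(rxn$lb)] <- -Inf
  rxn$ub[is.na(rxn$ub)] <- Inf
  net <- structure(list(metabolites = met[order(match(met$id, c(met_ids, met$id))), ],
                        reactions = rxn, stoich = stats::setNames(stoich, rxn$id)),
                   class = "sphingo_network")
  rownames(net$metabolites) <- NULL
  validate_network(net)
  net
}

#' Validate a network's internal consistency
#'
#' @param net `sphingo_network`
#' @return the network, invisibly; aborts on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "sphingo_network"))
  if (anyDuplicated(net$metabolites$id)) {
    sphingo_abort("validation", "duplicate metabolite ids")
  }
  used <- unique(unlist(lapply(net$stoich, names)))
  orphan <- setdiff(net$metabolites$id, used)
  orphan <- orphan[!net$metabolites$species_class[match(orphan, net$metabolites$id)] %in%
                     c("regulator", "boundary")]
  if (length(orphan)) {
    sphingo_abort("validation", "metabolite(s) appear in no reaction: ",
                  paste(orphan, collapse = ", "))
  }
  invisible(net)
}

#' Number of enzymatic reactions and associated genes
#' @param net `sphingo_network`
#' @return list with `n_enzymatic` and `n_genes`
#' @export
network_summary <- function(net) {
  enz <- net$reactions[net$reactions$type == "enzymatic", ]
  genes <- unlist(strsplit(enz$genes[!is.na(enz$genes) & nzchar(enz$genes)], "\\s*[,;]\\s*"))
  genes <- setdiff(unique(trimws(genes)), "")
  list(n_enzymatic = nrow(enz), n_genes = length(genes))
}

#' Build the stoichiometric matrix S (metabolites x reactions)
#'
#' @param net `sphingo_network`
#' @param trim drop buffered and boundary species rows (the mass-balance rows
#'   used by FBA); `FALSE` returns the full matrix.
#' @return numeric matrix with dimnames.
#' @export
build_stoichiometric_matrix <- function(net, trim = TRUE) {
  validate_network(net)
  mets <- net$metabolites
  S <- matrix(0, nrow = nrow(mets), ncol = nrow(net$reactions),
              dimnames = list(mets$id, net$reactions$id))
  for (j in seq_along(net$stoich)) {
    st <- net$stoich[[j]]
    S[names(st), j] <- st
  }
  if (trim) {
    drop <- mets$is_buffered | mets$species_class %in% c("boundary", "regulator")
    S <- S[!drop, , drop = FALSE]
  }
  S
}

#' Write a network back to the TSV dialect
#'
#' @param net `sphingo_network`
#' @param path output reaction TSV path
#' @param metabolites_path optional output metabolite TSV path
#' @export
write_network_tsv <- function(net, path, metabolites_path = NULL) {
  fmt_side <- function(st, sign) {
    sel <- if (sign < 0) st < 0 else st > 0
    if (!any(sel)) return("")
    paste(paste(format(abs(st[sel]), trim = TRUE, scientific = FALSE),
                names(st[sel])), collapse = " + ")
  }
  eq <- vapply(net$stoich, function(st) {
    paste(fmt_side(st, -1), "->", fmt_side(st, 1))
  }, character(1))
  out <- data.frame(rxn_id = net$reactions$id, enzyme = net$reactions$enzyme,
                    genes = net$reactions$genes, equation = eq,
                    delta_g0_kJ_mol = net$reactions$delta_g0,
                    lb = net$reactions$lb, ub = net$reactions$ub)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metabolites_path)) {
    utils::write.table(net$metabolites, metabolites_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.sphingo_network <- function(x, ...) {
  s <- network_summary(x)
  cat("<sphingo_network> ", nrow(x$reactions), " reactions (",
      s$n_enzymatic, " enzymatic, ", s$n_genes, " genes), ",
      nrow(x$metabolites), " metabolites (",
      sum(x$metabolites$is_buffered), " buffered)\n", sep = "")
  invisible(x)
}

#' Free (non-glycosylated) ceramide species of a network
#'
#' The pooled free-ceramide concentration is the regulating "ceramide" signal
#' used by ceramide-ORM and ceramide-SPT edges and by the screening filters.
#' @param net `sphingo_network`
#' @return character vector of metabolite ids
#' @export
free_ceramide_species <- function(net) {
  net$metabolites$id[net$metabolites$species_class %in% c("ceramide", "hydroxyceramide")]
}
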
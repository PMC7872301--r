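# Elementary mass-action decomposition of an enzymatic network.
#
# Every enzymatic reaction is expanded into the reversible chain
#   E (+ S) <-> E.S <-> E.P <-> E (+ P)
# i.e. three reversible steps / six elementary reactions. Buffered
# co-substrates (acyl-CoA pools, NADPH, UDP-glucose, serine) are folded into
# the enzyme complex, so chains carry at most one tracked substrate and one
# tracked product. Regulatory edges add:
#   inhibition:  E + I <-> E.I                (dead-end sequestration)
#   activation:  E + A <-> E.A                plus a full catalytic chain
#                                             rooted at E.A for each reaction
# Regulator-targeting edges (ceramide -| ORM) add R + pool-signal <-> R.pool.
# Regulatory steps are never counted among the metabolic elementary
# reactions. Species consumed by the biomass or export exchanges get a
# first-order sink step whose rate constant is fixed by the reference flux.

#' Decompose a network (plus regulatory scheme) into elementary reactions
#'
#' @param net `sphingo_network`
#' @param scheme `sphingo_scheme` (default: baseline ORM -| SPT only). Pass
#'   `new_scheme(NULL, add_baseline = FALSE)` for a purely metabolic system.
#' @return a `sphingo_elementary` object holding the species table, the
#'   elementary step table, per-enzyme state groups and per-reaction chains.
#' @export
decompose_to_elementary <- function(net, scheme = new_scheme(NULL)) {
  validate_network(net)
  validate_scheme(scheme, net)

  mets <- net$metabolites
  enz_rxns <- net$reactions[net$reactions$type == "enzymatic", ]
  enzymes <- unique(enz_rxns$enzyme)

  # --- species table ------------------------------------------------------
  sp <- data.frame(id = mets$id, kind = "metabolite", enzyme = NA_character_,
                   buffered = mets$is_buffered |
                     mets$species_class %in% c("boundary"),
                   stringsAsFactors = FALSE)

  add_sp <- function(id, kind, enzyme = NA_character_, buffered = FALSE) {
    sp <<- rbind(sp, data.frame(id = id, kind = kind, enzyme = enzyme,
                                buffered = buffered, stringsAsFactors = FALSE))
    nrow(sp)
  }

  edges <- scheme$edges
  enz_edges <- function(e) edges[edges$target == e, , drop = FALSE]

  # tracked substrate/product per reaction (at most one each)
  tracked <- !(mets$is_buffered | mets$species_class %in% c("boundary", "regulator"))
  names(tracked) <- mets$id
  rxn_ends <- lapply(seq_len(nrow(enz_rxns)), function(k) {
    st <- net$stoich[[enz_rxns$id[k]]]
    subs <- names(st)[st < 0 & tracked[names(st)]]
    prods <- names(st)[st > 0 & tracked[names(st)]]
    if (length(subs) > 1L || length(prods) > 1L) {
      sphingo_abort("mechanism", "reaction '", enz_rxns$id[k],
                    "' has >1 tracked substrate or product; fold co-substrates ",
                    "into the buffered set or split the reaction")
    }
    bad <- c(subs, prods)[abs(st[c(subs, prods)]) != 1]
    if (length(bad)) {
      sphingo_abort("mechanism", "non-unit tracked stoichiometry in '",
                    enz_rxns$id[k], "' for: ", paste(bad, collapse = ", "))
    }
    list(sub = if (length(subs)) subs else NA_character_,
         prod = if (length(prods)) prods else NA_character_)
  })
  names(rxn_ends) <- enz_rxns$id

  # --- allocate enzyme-state species (deterministic order) ----------------
  # Each reaction gets its own enzyme pool (free + complexes), matching the
  # per-reaction unit-sum constraint on the reference enzyme fractions.
  # Promiscuous enzymes are represented as one pool per catalyzed reaction;
  # regulatory edges on an enzyme apply to every one of its pools, and
  # perturbations scale all pools of the enzyme together.
  enzyme_states <- list()    # enzyme -> all state indices (all instances)
  instance_states <- list()  # rxn_id -> state indices of that reaction's pool
  chain_states <- list()     # per rxn x branch: list(root, c1, c2)
  ea_state <- list()         # rxn_id -> list(idx, regulator)
  inhib_states <- list()     # rxn_id -> named idx per regulator

  for (e in enzymes) {
    rids <- enz_rxns$id[enz_rxns$enzyme == e]
    ee <- enz_edges(e)
    inh <- ee[ee$mode == "inhibition", , drop = FALSE]
    act <- ee[ee$mode == "activation", , drop = FALSE]
    if (nrow(act) > 1L) {
      sphingo_abort("mechanism", "enzyme '", e, "' has more than one activator")
    }
    for (rid in rids) {
      idx_free <- add_sp(paste0("E:", rid), "enzyme_state", e)
      c1 <- add_sp(paste0("E:", rid, ":S"), "enzyme_state", e)
      c2 <- add_sp(paste0("E:", rid, ":P"), "enzyme_state", e)
      chain_states[[paste0(rid, "|basal")]] <- list(root = idx_free, c1 = c1, c2 = c2)
      states <- c(idx_free, c1, c2)
      st_inh <- integer(0)
      for (i in seq_len(nrow(inh))) {
        ei <- add_sp(paste0("E:", rid, ":", inh$regulator[i]), "enzyme_state", e)
        st_inh[inh$regulator[i]] <- ei
        states <- c(states, ei)
      }
      inhib_states[[rid]] <- st_inh
      if (nrow(act) == 1L) {
        ea <- add_sp(paste0("E:", rid, ":", act$regulator[1], "act"), "enzyme_state", e)
        ea_state[[rid]] <- list(idx = ea, regulator = act$regulator[1], enzyme = e)
        a1 <- add_sp(paste0("E:", rid, ":", act$regulator[1], "act:S"), "enzyme_state", e)
        a2 <- add_sp(paste0("E:", rid, ":", act$regulator[1], "act:P"), "enzyme_state", e)
        chain_states[[paste0(rid, "|activated")]] <- list(root = ea, c1 = a1, c2 = a2)
        states <- c(states, ea, a1, a2)
      }
      instance_states[[rid]] <- states
      enzyme_states[[e]] <- c(enzyme_states[[e]], states)
    }
  }

  # regulator-targeting edges (e.g. ceramide -| orm): sequestration complex
  reg_complexes <- list()
  reg_target_edges <- edges[edges$target %in%
                              mets$id[mets$species_class == "regulator"], , drop = FALSE]
  for (i in seq_len(nrow(reg_target_edges))) {
    ed <- reg_target_edges[i, ]
    cid <- add_sp(paste0("C:", ed$target, ":", ed$regulator), "regulator_complex")
    reg_complexes[[paste0(ed$regulator, "->", ed$target)]] <- cid
  }

  # --- pools --------------------------------------------------------------
  # Pooled signals weight each member by its reference abundance (taken from
  # the biomass composition when present): a normalized-concentration mean
  # would weight a trace species as heavily as a dominant one.
  abundance <- stats::setNames(rep(0, nrow(sp)), sp$id)
  bio_id <- net$reactions$id[net$reactions$type == "biomass"]
  if (length(bio_id)) {
    st <- net$stoich[[bio_id[1]]]
    cons <- -st[st < 0]
    abundance[names(cons)[names(cons) %in% names(abundance)]] <-
      cons[names(cons) %in% names(abundance)]
  }
  if (all(abundance == 0)) abundance[] <- 1
  pools <- list(ceramide = match(free_ceramide_species(net), sp$id))

  sp_idx <- stats::setNames(seq_len(nrow(sp)), sp$id)

  # --- step table ---------------------------------------------------------
  steps <- data.frame(rxn_id = character(0), enzyme = character(0),
                      branch = character(0), step = integer(0), dir = character(0),
                      type = character(0), r1 = integer(0), r2 = integer(0),
                      p1 = integer(0), p2 = integer(0), pool = character(0),
                      stringsAsFactors = FALSE)
  add_step <- function(rxn_id, enzyme, branch, step, dir, type,
                       r1, r2 = NA_integer_, p1 = NA_integer_, p2 = NA_integer_,
                       pool = NA_character_) {
    steps[nrow(steps) + 1L, ] <<- list(rxn_id, enzyme, branch, step, dir, type,
                                       r1, r2, p1, p2, pool)
    nrow(steps)
  }

  add_chain <- function(rid, e, branch, cs, type) {
    ends <- rxn_ends[[rid]]
    sub <- if (is.na(ends$sub)) NA_integer_ else sp_idx[[ends$sub]]
    prod <- if (is.na(ends$prod)) NA_integer_ else sp_idx[[ends$prod]]
    i1f <- add_step(rid, e, branch, 1L, "f", type, cs$root, sub, cs$c1)
    i1r <- add_step(rid, e, branch, 1L, "r", type, cs$c1, NA, cs$root, sub)
    i2f <- add_step(rid, e, branch, 2L, "f", type, cs$c1, NA, cs$c2)
    i2r <- add_step(rid, e, branch, 2L, "r", type, cs$c2, NA, cs$c1)
    i3f <- add_step(rid, e, branch, 3L, "f", type, cs$c2, NA, cs$root, prod)
    i3r <- add_step(rid, e, branch, 3L, "r", type, cs$root, prod, cs$c2)
    c(i1f, i1r, i2f, i2r, i3f, i3r)
  }

  chains <- list()
  reg_steps <- list()
  for (e in enzymes) {
    rids <- enz_rxns$id[enz_rxns$enzyme == e]
    for (rid in rids) {
      root <- chain_states[[paste0(rid, "|basal")]]$root
      rows <- add_chain(rid, e, "basal", chain_states[[paste0(rid, "|basal")]],
                        "metabolic")
      chains[[paste0(rid, "|basal")]] <- list(
        rxn_id = rid, enzyme = e, branch = "basal", rows = rows,
        states = chain_states[[paste0(rid, "|basal")]]
      )
      st_inh <- inhib_states[[rid]]
      for (reg in names(st_inh)) {
        ridx <- if (reg == "ceramide") NA_integer_ else sp_idx[[reg]]
        pool <- if (reg == "ceramide") "ceramide" else NA_character_
        f <- add_step(rid, e, NA_character_, NA_integer_, "f", "regulatory",
                      root, ridx, st_inh[[reg]], pool = pool)
        r <- add_step(rid, e, NA_character_, NA_integer_, "r", "regulatory",
                      st_inh[[reg]], NA, root, ridx)
        reg_steps[[paste0(reg, "-|", rid)]] <- list(
          kind = "inhibition", enzyme = e, rxn_id = rid, regulator = reg,
          f = f, r = r, root = root, complex = st_inh[[reg]]
        )
      }
      if (!is.null(ea_state[[rid]])) {
        ea <- ea_state[[rid]]
        ridx <- if (ea$regulator == "ceramide") NA_integer_ else sp_idx[[ea$regulator]]
        pool <- if (ea$regulator == "ceramide") "ceramide" else NA_character_
        f <- add_step(rid, e, NA_character_, NA_integer_, "f", "regulatory",
                      root, ridx, ea$idx, pool = pool)
        r <- add_step(rid, e, NA_character_, NA_integer_, "r", "regulatory",
                      ea$idx, NA, root, ridx)
        reg_steps[[paste0(ea$regulator, "->", rid)]] <- list(
          kind = "activation", enzyme = e, rxn_id = rid, regulator = ea$regulator,
          f = f, r = r, root = root, complex = ea$idx
        )
        rows <- add_chain(rid, e, "activated",
                          chain_states[[paste0(rid, "|activated")]], "regulatory")
        chains[[paste0(rid, "|activated")]] <- list(
          rxn_id = rid, enzyme = e, branch = "activated", rows = rows,
          states = chain_states[[paste0(rid, "|activated")]]
        )
      }
    }
  }

  for (nm in names(reg_complexes)) {
    ed <- strsplit(nm, "->", fixed = TRUE)[[1]]
    reg <- ed[1]; target <- ed[2]
    ridx <- if (reg == "ceramide") NA_integer_ else sp_idx[[reg]]
    pool <- if (reg == "ceramide") "ceramide" else NA_character_
    tidx <- sp_idx[[target]]
    f <- add_step(NA_character_, NA_character_, NA_character_, NA_integer_, "f",
                  "regulatory", tidx, ridx, reg_complexes[[nm]], pool = pool)
    r <- add_step(NA_character_, NA_character_, NA_character_, NA_integer_, "r",
                  "regulatory", reg_complexes[[nm]], NA, tidx, ridx)
    reg_steps[[nm]] <- list(kind = "sequestration", enzyme = NA_character_,
                            regulator = reg, target = target,
                            f = f, r = r, root = tidx, complex = reg_complexes[[nm]])
  }

  # --- sinks: species consumed by biomass or export exchanges -------------
  bio <- net$reactions$id[net$reactions$type == "biomass"]
  exch <- net$reactions$id[net$reactions$type == "exchange"]
  sink_species <- character(0)
  for (rid in c(bio, exch)) {
    st <- net$stoich[[rid]]
    cons <- names(st)[st < 0 & tracked[names(st)]]
    sink_species <- union(sink_species, cons)
  }
  sinks <- list()
  for (spid in sink_species) {
    i <- add_step(NA_character_, NA_character_, NA_character_, NA_integer_, "f",
                  "sink", sp_idx[[spid]])
    sinks[[spid]] <- list(species = sp_idx[[spid]], row = i)
  }

  # per-regulator conservation groups over dynamically partitioned states
  # (free form + sequestration complexes); occupancies are sampled per model
  reg_pools <- list()
  for (nm in names(reg_complexes)) {
    target <- strsplit(nm, "->", fixed = TRUE)[[1]][2]
    reg_pools[[target]] <- c(reg_pools[[target]] %||% sp_idx[[target]],
                             reg_complexes[[nm]])
  }

  # ORM-pool membership, used to apply regulator-level perturbations
  orm_ids <- mets$id[mets$species_class == "regulator"]
  orm_pool <- lapply(orm_ids, function(o) {
    member <- grepl(paste0("(^|:)", o, "(act)?(:|$)"), sp$id) | sp$id == o
    which(member)
  })
  names(orm_pool) <- orm_ids

  structure(list(
    species = sp, steps = steps, chains = chains, reg_steps = reg_steps,
    sinks = sinks, pools = pools, abundance = unname(abundance),
    orm_pool = orm_pool, reg_pools = reg_pools,
    enzyme_states = enzyme_states, instance_states = instance_states,
    ea_state = ea_state, network = net, scheme = scheme,
    n_metabolic = sum(steps$type == "metabolic"),
    n_regulatory = sum(steps$type == "regulatory")
  ), class = "sphingo_elementary")
}

#' @export
print.sphingo_elementary <- function(x, ...) {
  cat("<sphingo_elementary> ", x$n_metabolic, " metabolic + ", x$n_regulatory,
      " regulatory elementary reactions, ", nrow(x$species), " species (",
      sum(x$species$kind == "enzyme_state"), " enzyme states)\n", sep = "")
  invisible(x)
}

#' Compare an elementary decomposition's size against an expected count
#'
#' The metabolic elementary-reaction count depends on mechanism conventions
#' (how many reactions are multi-substrate, what is folded into the enzyme
#' complex). This helper reports any discrepancy as a diagnostic instead of
#' failing silently.
#'
#' @param elem `sphingo_elementary`
#' @param expected expected metabolic elementary reaction count
#' @return list with `observed`, `expected`, `difference` and a `message`
#' @export
elementary_count_diagnostic <- function(elem, expected) {
  obs <- elem$n_metabolic
  msg <- if (obs == expected) {
    sprintf("metabolic elementary count %d matches the expected %d", obs, expected)
  } else {
    sprintf(paste0("metabolic elementary count %d differs from the expected %d ",
                   "(difference %+d); counts are convention-dependent: this ",
                   "decomposition expands every enzymatic reaction into 6 ",
                   "elementary reactions with buffered co-substrates folded ",
                   "into the enzyme complex"), obs, expected, obs - expected)
  }
  list(observed = obs, expected = expected, difference = obs - expected, message = msg)
}
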
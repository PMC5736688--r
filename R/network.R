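# Reaction network generation.
#
# Species bookkeeping: every species row carries composition metadata used
# for conservation checks and phospho accounting:
#   adapters -- named counts of adapter units contained in the species
#   phospho  -- named counts of *phosphorylated* adapter copies (a
#               PTPN-bound phospho intermediate still counts: the adapter is
#               chemically phosphorylated until the catalytic step fires;
#               the post-catalysis [A:PTPN] complex does not)
#   receptor -- receptor unit contained (NA for none)
#
# Receptor state flags: "u" bound unphosphorylated, "p" phosphorylated,
# "q" phosphorylated with PTPN engaged.

FLAG_SUFFIX <- c(u = "", p = "~p", q = "~p:PTPN")

state_id <- function(receptor, occupancy, flags, residues) {
  if (!length(occupancy)) return(paste0("p", receptor))
  ord <- order(residues[names(occupancy)])
  toks <- paste0(names(occupancy)[ord], ":", unname(occupancy)[ord],
                 FLAG_SUFFIX[flags[ord]])
  paste0("p", receptor, "[", paste(toks, collapse = "|"), "]")
}

new_species_store <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

add_species <- function(store, id, kind, initial = 0, constant = FALSE,
                        receptor = NA_character_, adapters = numeric(),
                        phospho = numeric()) {
  if (!is.null(store$rows[[id]])) return(invisible(id))
  store$rows[[id]] <- list(id = id, kind = kind, initial = initial,
                           constant = constant, receptor = receptor,
                           adapters = adapters, phospho = phospho)
  invisible(id)
}

new_reaction_store <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

add_reaction <- function(store, label, rate, reactants, products) {
  if (rate < 0) stop_user("negative rate constant in reaction ", label)
  store$rows[[length(store$rows) + 1L]] <-
    list(label = label, rate = rate, reactants = reactants, products = products)
  invisible(NULL)
}

finalize_network <- function(species_store, reaction_store, params, variant) {
  sp <- species_store$rows
  species <- data.frame(
    id = vapply(sp, `[[`, "", "id"),
    kind = vapply(sp, `[[`, "", "kind"),
    initial = vapply(sp, `[[`, 0, "initial"),
    constant = vapply(sp, `[[`, TRUE, "constant"),
    receptor = vapply(sp, `[[`, "", "receptor"),
    stringsAsFactors = FALSE)
  species$adapters <- I(lapply(sp, `[[`, "adapters"))
  species$phospho <- I(lapply(sp, `[[`, "phospho"))
  rownames(species) <- species$id

  rx <- reaction_store$rows
  reactions <- data.frame(
    label = vapply(rx, `[[`, "", "label"),
    rate = vapply(rx, `[[`, 0, "rate"),
    stringsAsFactors = FALSE)
  reactions$reactants <- I(lapply(rx, `[[`, "reactants"))
  reactions$products <- I(lapply(rx, `[[`, "products"))

  net <- structure(list(species = species, reactions = reactions,
                        variant = variant,
                        params_digest = content_digest(params)),
                   class = "reaction_network")
  check_mass_balance(net)
  net
}

# every adapter/receptor unit on the left must appear on the right
check_mass_balance <- function(network) {
  sp <- network$species
  comp <- function(ids, field) {
    out <- numeric()
    for (id in ids) {
      v <- sp[id, field][[1]]
      for (nm in names(v)) {
        cur <- if (nm %in% names(out)) out[[nm]] else 0
        out[nm] <- cur + v[[nm]]
      }
    }
    out
  }
  same_counts <- function(la, ra) {
    nms <- union(names(la), names(ra))
    if (!length(nms)) return(TRUE)
    l <- stats::setNames(rep(0, length(nms)), nms); l[names(la)] <- la
    r <- stats::setNames(rep(0, length(nms)), nms); r[names(ra)] <- ra
    all(l == r)
  }
  rec_unit <- function(ids) {
    r <- sp[ids, "receptor"]
    r <- r[!is.na(r) & nzchar(r)]
    if (!length(r)) return(numeric())
    tb <- table(r)
    stats::setNames(as.numeric(tb), names(tb))
  }
  for (i in seq_len(nrow(network$reactions))) {
    lhs <- network$reactions$reactants[[i]]
    rhs <- network$reactions$products[[i]]
    if (!same_counts(comp(lhs, "adapters"), comp(rhs, "adapters"))) {
      stop("mass balance violated for adapters in reaction ",
           network$reactions$label[i])
    }
    if (!same_counts(rec_unit(lhs), rec_unit(rhs))) {
      stop("mass balance violated for receptors in reaction ",
           network$reactions$label[i])
    }
  }
  invisible(TRUE)
}

add_common_species <- function(store, params) {
  add_species(store, "VEGF", "ligand",
              initial = ligand_molecules(params$ligand, params$cell_volume),
              constant = !params$ligand$depletable)
  add_species(store, "PTPN", "phosphatase",
              initial = params$phosphatase$reservoir, constant = TRUE)
  for (a in params$adapters) {
    add_species(store, a$name, "free_adapter", initial = a$concentration,
                adapters = stats::setNames(1, a$name))
    add_species(store, paste0(a$name, ":PTPN"), "adapter_phosphatase_complex",
                adapters = stats::setNames(1, a$name))
  }
}

# adapters that can engage a receptor at all (have >= 1 site on it)
binders_of <- function(params, receptor_name) {
  keep <- vapply(params$adapters, function(a) {
    length(a$site_names[[receptor_name]] %||% character()) > 0
  }, TRUE)
  params$adapters[keep]
}

#' Build the nonspecific single-site reaction network
#'
#' In the nonspecific model every adapter competes for one generic
#' phospho-tyrosine site per receptor, so at most one adapter is bound to a
#' receptor at a time. For each receptor R and each adapter A able to bind
#' it, the scheme comprises: `VEGF + R <-> pR` (receptor activation is
#' lumped into ligand binding), `pR + A <-> [pR:A]`, `[pR:A] -> [pR:pA]` at
#' the shared phosphorylation rate kp, `[pR:pA] + PTPN <-> [pR:pA:PTPN]`,
#' the catalytic release `[pR:pA:PTPN] -> pR + [A:PTPN]`, and the recycling
#' step `[A:PTPN] -> A + PTPN` that closes the adapter cycle.
#'
#' @param params A validated `model_parameters` object.
#' @return A `reaction_network`.
#' @export
build_nonspecific_network <- function(params) {
  validate_parameters(params)
  sp <- new_species_store(); rx <- new_reaction_store()
  add_common_species(sp, params)
  ph <- params$phosphatase
  for (r in params$receptors) {
    R <- r$name; pR <- paste0("p", R)
    add_species(sp, R, "free_receptor", initial = r$concentration, receptor = R)
    add_species(sp, pR, "phospho_receptor_complex", receptor = R)
    add_reaction(rx, paste0("VEGF binding ", R), r$kon_vegf, c("VEGF", R), pR)
    add_reaction(rx, paste0("VEGF release ", R), r$koff_vegf, pR, c("VEGF", R))
    for (a in binders_of(params, R)) {
      A <- a$name
      C <- paste0("[", pR, ":", A, "]")
      Cp <- paste0("[", pR, ":p", A, "]")
      Cq <- paste0("[", pR, ":p", A, ":PTPN]")
      one <- stats::setNames(1, A)
      add_species(sp, C, "phospho_receptor_complex", receptor = R, adapters = one)
      add_species(sp, Cp, "phospho_receptor_complex", receptor = R,
                  adapters = one, phospho = one)
      add_species(sp, Cq, "phospho_receptor_complex", receptor = R,
                  adapters = one, phospho = one)
      add_reaction(rx, paste0(A, " binding ", R), a$kon, c(pR, A), C)
      add_reaction(rx, paste0(A, " release ", R), a$koff, C, c(pR, A))
      if (!a$inhibited && params$kp > 0) {
        add_reaction(rx, paste0(A, " phosphorylation on ", R), params$kp, C, Cp)
      }
      add_reaction(rx, paste0("PTPN binding p", A, " on ", R), ph$kon,
                   c(Cp, "PTPN"), Cq)
      add_reaction(rx, paste0("PTPN release from p", A, " on ", R), ph$koff,
                   Cq, c(Cp, "PTPN"))
      add_reaction(rx, paste0("dephosphorylation of ", A, " on ", R), ph$kd,
                   Cq, c(pR, paste0(A, ":PTPN")))
    }
  }
  for (a in params$adapters) {
    add_reaction(rx, paste0(a$name, ":PTPN recycling"), ph$koff,
                 paste0(a$name, ":PTPN"), c(a$name, "PTPN"))
  }
  finalize_network(sp, rx, params, "nonspecific")
}

#' Build the site-specific reaction network
#'
#' Receptor species are phospho-receptor states annotated with a sterically
#' feasible occupancy: which adapter sits at which tyrosine site, and for
#' each bound adapter whether it is unphosphorylated, phosphorylated, or
#' phosphorylated with PTPN engaged. Binding reactions connect a state to
#' each feasible superstate at the adapter's kon/koff; phosphorylation (kp)
#' flips a bound adapter's flag; PTPN binding and the catalytic release
#' follow the same scheme as the nonspecific model, applied per bound
#' phospho-adapter. Only transitions between feasible states exist.
#'
#' @param params A validated `model_parameters` object.
#' @param configs Optional list of feasible [binding_configuration()]s per
#'   receptor (as returned by [enumerate_configurations()]); enumerated
#'   internally when `NULL`.
#' @return A `reaction_network`.
#' @export
build_specific_network <- function(params, configs = NULL) {
  validate_parameters(params)
  sp <- new_species_store(); rx <- new_reaction_store()
  add_common_species(sp, params)
  ph <- params$phosphatase; kp <- params$kp

  for (r in params$receptors) {
    R <- r$name
    residues <- r$sites
    add_species(sp, R, "free_receptor", initial = r$concentration, receptor = R)
    cfgs <- if (is.null(configs)) enumerate_configurations(r, params)
            else Filter(function(cf) cf$receptor == R, configs)
    if (!length(cfgs)) stop("no feasible configurations supplied for receptor ", R)
    feas_key <- vapply(cfgs, function(cf) {
      paste(sort(paste0(names(cf$occupancy), "=", cf$occupancy)), collapse = ";")
    }, "")
    is_feasible_occ <- function(occ) {
      key <- paste(sort(paste0(names(occ), "=", occ)), collapse = ";")
      key %in% feas_key
    }

    # enumerate states: feasible configs x per-adapter flags
    states <- list()
    for (cf in cfgs) {
      occ <- cf$occupancy
      k <- length(occ)
      flag_sets <- if (k == 0) list(character()) else {
        grid <- do.call(expand.grid, c(rep(list(c("u", "p", "q")), k),
                                       stringsAsFactors = FALSE))
        lapply(seq_len(nrow(grid)), function(i) {
          stats::setNames(as.character(grid[i, ]), names(occ))
        })
      }
      for (fl in flag_sets) {
        id <- state_id(R, occ, fl[names(occ)] %||% character(), residues)
        n_ad <- table(unname(occ))
        adapters <- stats::setNames(as.numeric(n_ad), names(n_ad))
        ph_occ <- occ[names(fl)[fl %in% c("p", "q")]]
        n_ph <- table(unname(ph_occ))
        phospho <- stats::setNames(as.numeric(n_ph), names(n_ph))
        add_species(sp, id, "phospho_receptor_complex", receptor = R,
                    adapters = adapters, phospho = phospho)
        states[[length(states) + 1L]] <- list(id = id, occ = occ, flags = fl)
      }
    }

    pR <- state_id(R, character(), character(), residues)
    add_reaction(rx, paste0("VEGF binding ", R), r$kon_vegf, c("VEGF", R), pR)
    add_reaction(rx, paste0("VEGF release ", R), r$koff_vegf, pR, c("VEGF", R))

    for (st in states) {
      occ <- st$occ; fl <- st$flags
      # adapter binding into each free, allowed, feasible site
      for (s in setdiff(names(residues), names(occ))) {
        for (a in binders_of(params, R)) {
          if (!s %in% a$site_names[[R]]) next
          occ2 <- c(occ, stats::setNames(a$name, s))
          if (!is_feasible_occ(occ2)) next
          fl2 <- c(fl, stats::setNames("u", s))
          target <- state_id(R, occ2, fl2[names(occ2)], residues)
          add_reaction(rx, paste0(a$name, " binding ", R, "@", s),
                       a$kon, c(st$id, a$name), target)
        }
      }
      # per bound adapter moves
      for (s in names(occ)) {
        A <- occ[[s]]
        f <- fl[[s]]
        if (f == "u") {
          occ2 <- occ[setdiff(names(occ), s)]
          fl2 <- fl[setdiff(names(fl), s)]
          src <- state_id(R, occ2, fl2[names(occ2)], residues)
          koff <- get_adapter(params, A)$koff
          add_reaction(rx, paste0(A, " release ", R, "@", s), koff,
                       st$id, c(src, A))
          if (!get_adapter(params, A)$inhibited && kp > 0) {
            fl2 <- fl; fl2[[s]] <- "p"
            add_reaction(rx, paste0(A, " phosphorylation ", R, "@", s), kp,
                         st$id, state_id(R, occ, fl2[names(occ)], residues))
          }
        } else if (f == "p") {
          fl2 <- fl; fl2[[s]] <- "q"
          add_reaction(rx, paste0("PTPN binding p", A, " ", R, "@", s), ph$kon,
                       c(st$id, "PTPN"), state_id(R, occ, fl2[names(occ)], residues))
        } else { # q
          fl2 <- fl; fl2[[s]] <- "p"
          add_reaction(rx, paste0("PTPN release from p", A, " ", R, "@", s),
                       ph$koff, st$id,
                       c(state_id(R, occ, fl2[names(occ)], residues), "PTPN"))
          occ2 <- occ[setdiff(names(occ), s)]
          fl3 <- fl[setdiff(names(fl), s)]
          add_reaction(rx, paste0("dephosphorylation of ", A, " ", R, "@", s),
                       ph$kd, st$id,
                       c(state_id(R, occ2, fl3[names(occ2)], residues),
                         paste0(A, ":PTPN")))
        }
      }
    }
  }
  for (a in params$adapters) {
    add_reaction(rx, paste0(a$name, ":PTPN recycling"), params$phosphatase$koff,
                 paste0(a$name, ":PTPN"), c(a$name, "PTPN"))
  }
  finalize_network(sp, rx, params, "specific")
}

#' Build a reaction network for either model variant
#'
#' @param params A `model_parameters` object.
#' @param variant `"specific"` (site-resolved with steric constraints) or
#'   `"nonspecific"` (single generic site).
#' @return A `reaction_network`.
#' @export
build_network <- function(params, variant = c("specific", "nonspecific")) {
  variant <- match.arg(variant)
  if (variant == "specific") build_specific_network(params)
  else build_nonspecific_network(params)
}

#' Stoichiometry matrix of a reaction network
#'
#' @param network A `reaction_network`.
#' @return Integer matrix, species (rows, named) by reactions (columns):
#'   products minus reactants with multiplicity.
#' @export
stoichiometry_matrix <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  ids <- network$species$id
  n_rx <- nrow(network$reactions)
  S <- matrix(0L, nrow = length(ids), ncol = n_rx,
              dimnames = list(ids, network$reactions$label))
  for (j in seq_len(n_rx)) {
    for (id in network$reactions$reactants[[j]]) {
      S[id, j] <- S[id, j] - 1L
    }
    for (id in network$reactions$products[[j]]) {
      S[id, j] <- S[id, j] + 1L
    }
  }
  S
}

#' Moiety conservation vector for an adapter or receptor
#'
#' Returns the left-null-space vector counting how many units of the given
#' moiety each species contains; `w %*% S` is identically zero for adapter
#' and receptor moieties (ligand and phosphatase are boundary species with
#' their own treatments and have no such law).
#'
#' @param network A `reaction_network`.
#' @param moiety Adapter or receptor name.
#' @return Named numeric vector over species.
#' @export
conservation_vector <- function(network, moiety) {
  sp <- network$species
  w <- vapply(seq_len(nrow(sp)), function(i) {
    cnt <- 0
    if (!is.na(sp$receptor[i]) && sp$receptor[i] == moiety) cnt <- cnt + 1
    ad <- sp$adapters[[i]]
    if (moiety %in% names(ad)) cnt <- cnt + ad[[moiety]]
    cnt
  }, 0)
  stats::setNames(w, sp$id)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network (", x$variant, "): ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Export species and reaction tables
#'
#' @param network A `reaction_network`.
#' @return `species_table`: data frame of id, kind, initial amount,
#'   constant flag; `reactions_table`: data frame of label, rate constant,
#'   and `+`-joined reactant/product lists.
#' @export
species_table <- function(network) {
  network$species[, c("id", "kind", "initial", "constant")]
}

#' @rdname species_table
#' @export
reactions_table <- function(network) {
  data.frame(
    label = network$reactions$label,
    rate = network$reactions$rate,
    reactants = vapply(network$reactions$reactants, paste, "", collapse = " + "),
    products = vapply(network$reactions$products, paste, "", collapse = " + "),
    stringsAsFactors = FALSE)
}

#' Collapse a parameter set to a single shared exclusive site
#'
#' Utility for the reduction equivalence between model variants: replaces
#' every receptor's tyrosine sites with one generic site that all of its
#' binders map to. Building the specific network from the collapsed
#' parameters yields dynamics identical to the nonspecific network of the
#' original parameters.
#'
#' @param params A `model_parameters` object.
#' @return A `model_parameters` object with one site per receptor.
#' @export
collapse_to_single_site <- function(params) {
  p <- params
  for (i in seq_along(p$receptors)) {
    r <- p$receptors[[i]]
    p$receptors[[i]]$sites <- stats::setNames(1000, "Ynsp")
  }
  for (i in seq_along(p$adapters)) {
    sn <- p$adapters[[i]]$site_names
    for (rn in names(sn)) {
      if (length(sn[[rn]])) sn[[rn]] <- "Ynsp"
    }
    p$adapters[[i]]$site_names <- sn
  }
  validate_parameters(p)
  p
}
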
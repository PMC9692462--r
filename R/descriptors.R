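#' Mechanism descriptors from species enthalpies
#'
#' The three radical-scavenging mechanisms of an antioxidant AXH are
#' characterized by five reaction enthalpies:
#' \itemize{
#'   \item HAT: `BDE = H(AX.) + H(H.) - H(AXH)`
#'   \item SET-PT step 1: `IP = H(AXH+.) + H(e-) - H(AXH)`
#'   \item SET-PT step 2: `PDE = H(AX.) + H(H+) - H(AXH+.)`
#'   \item SPLET step 1: `PA = H(AX-) + H(H+) - H(AXH)`
#'   \item SPLET step 2: `ETE = H(AX.) + H(e-) - H(AX-)`
#' }
#' All descriptors are balanced reaction enthalpies, hence invariant under
#' a uniform shift of the species enthalpies.  Gibbs energies satisfy the
#' same relations; the quantity kind is a dataset-level tag, not a
#' different code path.
#'
#' @name descriptors
NULL

.species_roles <- c("AXH", "AX_radical", "AX_anion", "AXH_cation")

#' Bundle per-site species enthalpies
#'
#' @param molecule_id,site_id Identifiers (site e.g. `"1-OH"`, `"4-NH"`).
#' @param H_AXH,H_AXrad,H_AXanion,H_AXHcation Enthalpies of the parent
#'   molecule, its H-abstraction radical, its deprotonated anion and its
#'   radical cation.  `energy_value`s or plain numerics in `unit`.
#'   The anion and cation are optional; descriptors needing an absent
#'   species come out `NA`.
#' @param unit Unit of any plain-numeric enthalpy.
#' @return List of class `species_enthalpies` with all enthalpies in
#'   kJ/mol.
#' @export
species_enthalpies <- function(molecule_id, site_id, H_AXH, H_AXrad,
                               H_AXanion = NULL, H_AXHcation = NULL,
                               unit = "kJ/mol") {
  tokj <- function(x) {
    if (is.null(x) || (length(x) == 1 && !inherits(x, "energy_value") &&
                       is.na(x))) return(NA_real_)
    if (inherits(x, "energy_value")) as.numeric(convert_energy(x, "kJ/mol"))
    else as.numeric(convert_energy(x, to = "kJ/mol", from = unit))
  }
  structure(list(molecule_id = as.character(molecule_id),
                 site_id = as.character(site_id),
                 H_AXH = tokj(H_AXH), H_AXrad = tokj(H_AXrad),
                 H_AXanion = tokj(H_AXanion), H_AXHcation = tokj(H_AXHcation)),
            class = "species_enthalpies")
}

# reference-particle enthalpies in a medium, kJ/mol
.ref_particles_in_medium <- function(functional, basis, medium, catalog) {
  med <- if (inherits(medium, "medium")) medium else get_medium(medium, catalog)
  list(
    H_hatom = as.numeric(convert_energy(lookup_h_atom(functional, basis, catalog),
                                        "kJ/mol")) + med$dH_solv_hatom,
    H_proton = catalog$reference$H_proton_gas + med$dH_solv_proton,
    H_electron = catalog$reference$H_electron_gas + med$dH_solv_electron,
    medium_name = med$name
  )
}

#' Compute the five descriptors for one H-donation site
#'
#' @param species A `species_enthalpies` object.
#' @param functional,basis Method key resolving the H-atom enthalpy.
#' @param medium Medium name or `medium` record.
#' @param catalog A `media_catalog`.
#' @return One-row `descriptor_table` (kJ/mol).  Descriptors whose species
#'   are absent are `NA`, never zero.  PA may legitimately be negative.
#' @export
compute_descriptors <- function(species, functional, basis, medium = "gas",
                                catalog = media_catalog()) {
  stopifnot(inherits(species, "species_enthalpies"))
  if (!is.finite(species$H_AXH) || !is.finite(species$H_AXrad))
    stop("H_AXH and H_AXrad are required", call. = FALSE)
  ref <- .ref_particles_in_medium(functional, basis, medium, catalog)
  BDE <- species$H_AXrad + ref$H_hatom - species$H_AXH
  IP  <- if (is.finite(species$H_AXHcation))
    species$H_AXHcation + ref$H_electron - species$H_AXH else NA_real_
  PDE <- if (is.finite(species$H_AXHcation))
    species$H_AXrad + ref$H_proton - species$H_AXHcation else NA_real_
  PA  <- if (is.finite(species$H_AXanion))
    species$H_AXanion + ref$H_proton - species$H_AXH else NA_real_
  ETE <- if (is.finite(species$H_AXanion))
    species$H_AXrad + ref$H_electron - species$H_AXanion else NA_real_
  d <- data.frame(molecule_id = species$molecule_id, site_id = species$site_id,
                  medium = ref$medium_name, unit = "kJ/mol",
                  BDE = BDE, IP = IP, PDE = PDE, PA = PA, ETE = ETE,
                  SETPT = NA_real_, SPLET = NA_real_,
                  stringsAsFactors = FALSE)
  combined_sums(as_descriptor_table(d))
}

#' Compute descriptors for a whole species table
#'
#' @param species_table Long-format data.frame with columns `molecule_id`,
#'   `site_id`, `species_role` (one of AXH, AX_radical, AX_anion,
#'   AXH_cation), `energy`, `unit`.
#' @inheritParams compute_descriptors
#' @return `descriptor_table`, one row per (molecule, site).
#' @export
compute_descriptor_table <- function(species_table, functional, basis,
                                     medium = "gas", catalog = media_catalog()) {
  need <- c("molecule_id", "site_id", "species_role", "energy", "unit")
  missing <- setdiff(need, names(species_table))
  if (length(missing))
    stop("species table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(species_table$species_role), .species_roles)
  if (length(bad))
    stop("unknown species_role: ", paste(bad, collapse = ", "), call. = FALSE)
  keys <- unique(species_table[, c("molecule_id", "site_id")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- species_table[species_table$molecule_id == keys$molecule_id[i] &
                         species_table$site_id == keys$site_id[i], ]
    pick <- function(role) {
      j <- which(sub$species_role == role)
      if (!length(j)) return(NULL)
      convert_energy(sub$energy[j[1]], to = "kJ/mol", from = sub$unit[j[1]])
    }
    sp <- species_enthalpies(keys$molecule_id[i], keys$site_id[i],
                             H_AXH = pick("AXH"), H_AXrad = pick("AX_radical"),
                             H_AXanion = pick("AX_anion"),
                             H_AXHcation = pick("AXH_cation"))
    compute_descriptors(sp, functional, basis, medium, catalog)
  })
  out <- do.call(rbind, rows)
  # IP is a property of the parent molecule, not of the site: fan the
  # molecule-level value out to rows whose cation was only given once
  for (m in unique(out$molecule_id)) {
    sel <- out$molecule_id == m
    ipv <- out$IP[sel]
    if (any(is.finite(ipv)) && any(!is.finite(ipv)))
      out$IP[sel][!is.finite(out$IP[sel])] <- ipv[is.finite(ipv)][1]
  }
  combined_sums(as_descriptor_table(out))
}

#' Coerce a data.frame to a descriptor table
#' @param d data.frame with at least molecule_id, site_id, medium, unit
#'   and a subset of BDE, IP, PDE, PA, ETE, SETPT, SPLET, IPH.
#' @return `descriptor_table`.
#' @export
as_descriptor_table <- function(d) {
  stopifnot(is.data.frame(d))
  for (col in c("BDE", "IP", "PDE", "PA", "ETE", "SETPT", "SPLET"))
    if (is.null(d[[col]])) d[[col]] <- rep(NA_real_, nrow(d))
  class(d) <- unique(c("descriptor_table", class(d)))
  d
}

#' Fill combined pathway sums from components
#'
#' `SETPT = IP + PDE` and `SPLET = PA + ETE`.  Reported sums are left
#' untouched; computed sums are stored alongside in `SETPT_calc` /
#' `SPLET_calc`, and only `NA` reported slots are filled from them.
#'
#' @param d `descriptor_table`.
#' @return `descriptor_table` with `SETPT_calc`, `SPLET_calc` added.
#' @export
combined_sums <- function(d) {
  d <- as_descriptor_table(d)
  # remember which totals were genuinely reported (vs filled from addends):
  # audit tolerances count independently rounded terms
  if (is.null(d$SETPT_is_reported)) d$SETPT_is_reported <- !is.na(d$SETPT)
  if (is.null(d$SPLET_is_reported)) d$SPLET_is_reported <- !is.na(d$SPLET)
  d$SETPT_calc <- ifelse(is.finite(d$IP) & is.finite(d$PDE), d$IP + d$PDE, NA_real_)
  d$SPLET_calc <- ifelse(is.finite(d$PA) & is.finite(d$ETE), d$PA + d$ETE, NA_real_)
  fill <- is.na(d$SETPT) & !is.na(d$SETPT_calc)
  d$SETPT[fill] <- d$SETPT_calc[fill]
  fill <- is.na(d$SPLET) & !is.na(d$SPLET_calc)
  d$SPLET[fill] <- d$SPLET_calc[fill]
  d
}

#' Fan a molecule-level IP out to all site rows
#'
#' Published tables often print IP once per molecule (ionization is a
#' property of the parent molecule, not of the H-donation site); this
#' fills the blank site rows from the molecule's value.
#'
#' @param d `descriptor_table`.
#' @return `descriptor_table` with IP filled per molecule.
#' @export
fill_molecule_ip <- function(d) {
  d <- as_descriptor_table(d)
  for (m in unique(d$molecule_id)) {
    sel <- d$molecule_id == m
    ipv <- d$IP[sel]
    if (any(is.finite(ipv)))
      d$IP[sel][!is.finite(ipv)] <- ipv[is.finite(ipv)][1]
  }
  combined_sums(d)
}

#' Evaluate the four step-descriptor ordering biconditionals
#'
#' The pathway identity IP+PDE = PA+ETE forces four orderings: IP<PA iff
#' PDE>ETE, IP>PA iff PDE<ETE, IP<ETE iff PDE>PA, IP>ETE iff PDE<PA.
#' A descriptor set satisfying the identity exactly can never violate any
#' of them; a violation indicates an inconsistent table.
#'
#' @param d One-row `descriptor_table` (or data.frame row) with the four
#'   step descriptors.
#' @param tie_tol Differences at or below this magnitude (same unit as the
#'   table) are reported `tied` rather than compared.
#' @return data.frame with columns `check` (C1a..C1d) and `verdict`
#'   (`consistent`, `violated`, `tied`).
#' @export
corollary_orderings <- function(d, tie_tol = 1e-9) {
  stopifnot(nrow(d) == 1)
  if (!all(is.finite(c(d$IP, d$PA, d$PDE, d$ETE))))
    stop("all four step descriptors (IP, PA, PDE, ETE) required", call. = FALSE)
  lhs <- c(C1a = d$IP - d$PA, C1b = d$IP - d$PA,
           C1c = d$IP - d$ETE, C1d = d$IP - d$ETE)
  rhs <- c(C1a = d$ETE - d$PDE, C1b = d$ETE - d$PDE,
           C1c = d$PA - d$PDE, C1d = d$PA - d$PDE)
  want_neg <- c(C1a = TRUE, C1b = FALSE, C1c = TRUE, C1d = FALSE)
  verdict <- vapply(names(lhs), function(k) {
    if (abs(lhs[k]) <= tie_tol || abs(rhs[k]) <= tie_tol) return("tied")
    l <- if (want_neg[k]) lhs[k] < 0 else lhs[k] > 0
    r <- if (want_neg[k]) rhs[k] < 0 else rhs[k] > 0
    if (identical(unname(l), unname(r))) "consistent" else "violated"
  }, "")
  data.frame(check = names(lhs), verdict = unname(verdict),
             stringsAsFactors = FALSE)
}
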
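#' Synthetic species/descriptor fixtures with controlled fault injection
#'
#' The generator draws descriptor targets inside realistic windows
#' (BDE in 300-500 kJ/mol, IP in 500-900 kJ/mol, PA in 50-700 kJ/mol --
#' the spread seen across published antioxidant tables) and solves for
#' species enthalpies that reproduce them exactly, so every generated
#' table satisfies both pathway identities to floating-point precision by
#' construction.  It emulates table structure and error classes, not the
#' underlying electronic-structure physics.
#'
#' @name fixture_gen
NULL

# run code under a fixed seed without touching global RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a consistent synthetic species + descriptor table
#'
#' @param n_molecules,sites_per_molecule Positive integers.
#' @param medium Medium name.
#' @param functional,basis Method key for the reference particles.
#' @param seed Integer seed; the same seed reproduces identical tables.
#' @param catalog A `media_catalog`.
#' @return List with `species` (long-format data.frame), `descriptors`
#'   (`descriptor_table`, kJ/mol), and the `iph_kj` of the generating
#'   medium/method.
#' @export
generate_consistent <- function(n_molecules, sites_per_molecule,
                                medium = "water", functional = "B3LYP",
                                basis = "6-311++G(d,p)", seed = 1,
                                catalog = media_catalog()) {
  if (n_molecules < 1 || sites_per_molecule < 1)
    stop("n_molecules and sites_per_molecule must be >= 1", call. = FALSE)
  ref <- .ref_particles_in_medium(functional, basis, medium, catalog)
  species <- .with_seed(seed, {
    rows <- list()
    for (m in seq_len(n_molecules)) {
      mol <- sprintf("mol%02d", m)
      H_AXH <- stats::runif(1, -2.1e6, -1.9e6)
      IP <- stats::runif(1, 500, 900)
      H_cat <- IP + H_AXH - ref$H_electron
      rows[[length(rows) + 1]] <- data.frame(
        molecule_id = mol, site_id = "", species_role = c("AXH", "AXH_cation"),
        energy = c(H_AXH, H_cat), unit = "kJ/mol", stringsAsFactors = FALSE)
      for (s in seq_len(sites_per_molecule)) {
        site <- sprintf("%d-OH", s)
        BDE <- stats::runif(1, 300, 500)
        PA <- stats::runif(1, 50, 700)
        H_rad <- BDE + H_AXH - ref$H_hatom
        H_an <- PA + H_AXH - ref$H_proton
        rows[[length(rows) + 1]] <- data.frame(
          molecule_id = mol, site_id = site,
          species_role = c("AX_radical", "AX_anion"),
          energy = c(H_rad, H_an), unit = "kJ/mol", stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  # fan molecule-level species out to each site
  persite <- species[species$site_id != "", ]
  permol <- species[species$site_id == "", ]
  long <- rbind(persite,
                do.call(rbind, lapply(unique(persite$site_id), function(s) {
                  x <- permol[permol$molecule_id %in%
                                persite$molecule_id[persite$site_id == s], ]
                  x$site_id <- s
                  x
                })))
  long <- unique(long[long$site_id != "", ])
  d <- compute_descriptor_table(long, functional, basis, medium, catalog)
  list(species = long, descriptors = d,
       iph_kj = as.numeric(iph(functional, basis, medium, catalog = catalog)),
       medium = medium, functional = functional, basis = basis, seed = seed)
}

.violation_kinds <- c("none", "t1_offset", "t2_offset", "unit_mixup",
                      "medium_mislabel", "transcription_error")

#' Inject a labeled violation into a descriptor table
#'
#' @param d `descriptor_table` (e.g. `generate_consistent(...)$descriptors`).
#' @param kind One of `none`, `t1_offset` (shifts PDE only, breaking the
#'   pathway equality), `t2_offset` (shifts PDE and ETE alike, preserving
#'   the equality but shifting the IP+PDE-BDE offset), `unit_mixup`
#'   (multiplies the SPLET-side cells by 4.184, as when kcal values land
#'   in a kJ column), `medium_mislabel` (rewrites the declared medium
#'   only), `transcription_error` (corrupts the reported SETPT sum).
#' @param magnitude Offset magnitude, kJ/mol (where applicable), >= 0.
#' @param rows Integer indices of target rows.
#' @param to_medium Replacement medium for `medium_mislabel`.
#' @return List with `table` (modified `descriptor_table`) and `truth`
#'   (data.frame of row indices and the check expected to fire).
#' @export
inject_violation <- function(d, kind, magnitude = 0, rows = 1,
                             to_medium = NULL) {
  d <- combined_sums(as_descriptor_table(d))
  kind <- match.arg(kind, .violation_kinds)
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  if (kind == "none")
    return(list(table = d, truth = data.frame(row = integer(),
                                              check = character())))
  rows <- as.integer(rows)
  if (!length(rows) || any(rows < 1 | rows > nrow(d)))
    stop("row selection matches no rows of the table", call. = FALSE)
  refresh <- function(d) { d$SETPT <- d$SETPT_calc <- d$IP + d$PDE
                           d$SPLET <- d$SPLET_calc <- d$PA + d$ETE; d }
  truth_check <- switch(kind,
    t1_offset = "T1", t2_offset = "T2_reference", unit_mixup = "T1",
    medium_mislabel = "T2_reference", transcription_error = "transcription_SETPT")
  if (kind == "t1_offset") {
    d$PDE[rows] <- d$PDE[rows] + magnitude
    d <- refresh(d)
  } else if (kind == "t2_offset") {
    d$PDE[rows] <- d$PDE[rows] + magnitude
    d$ETE[rows] <- d$ETE[rows] + magnitude
    d <- refresh(d)
  } else if (kind == "unit_mixup") {
    f <- energy_constants()$kcal_in_kJ
    for (col in c("PA", "ETE")) d[[col]][rows] <- d[[col]][rows] * f
    d <- refresh(d)
  } else if (kind == "medium_mislabel") {
    if (is.null(to_medium)) stop("to_medium required", call. = FALSE)
    d$medium[rows] <- to_medium
  } else if (kind == "transcription_error") {
    d$SETPT[rows] <- d$SETPT[rows] + magnitude
  }
  list(table = d,
       truth = data.frame(row = rows, check = truth_check,
                          stringsAsFactors = FALSE))
}
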
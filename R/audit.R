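#' Auditing reported descriptor tables
#'
#' Two exact identities constrain any correctly computed descriptor set:
#' the combined two-step pathway enthalpies are equal (T1: IP+PDE =
#' PA+ETE), and both exceed BDE by exactly the H-atom ionization enthalpy
#' of the medium (T2: IP+PDE - BDE = IPH, the same positive value for
#' every molecule and site in one medium).  The audit engine evaluates
#' these with rounding-aware tolerances, plus the ordering corollaries
#' and the positivity bound BDE < IP+PDE, and attaches diagnoses for the
#' common failure modes: unit mix-ups (a 4.184 rescale fixes the
#' residual), gas/solvent mislabeling (the IP+PDE-BDE offset matches a
#' different medium's IPH), or gross inconsistency.
#'
#' T2 is tested in two tiers.  Site-invariance (the offset is identical
#' across rows) is exact and reference-free; the comparison against a
#' catalog IPH value is loose (default 5 kJ/mol), because the offset
#' depends slightly on how the H-atom was treated in the solvent model,
#' while site-invariance does not.
#'
#' @name audit
NULL

#' Audit configuration
#'
#' @param printed_decimals Decimals the audited table prints (global).
#' @param tolerance_mode `"printed_precision"`: tolerance for a residual
#'   combining k independently rounded terms is `k * 0.5 * 10^-decimals`
#'   (in the table's unit); `"absolute"`: use `absolute_tol`.
#' @param absolute_tol Absolute tolerance, kJ/mol.
#' @param iph_proximity_tol Loose tolerance for the T2 reference check,
#'   kJ/mol.
#' @param iph_override Optional per-dataset IPH reference value, in the
#'   audited table's unit; overrides both per-row references and the
#'   catalog.
#' @param functional,basis Optional method key for catalog IPH lookups.
#' @param catalog A `media_catalog`.
#' @return List of class `audit_config`.
#' @export
audit_config <- function(printed_decimals = 1,
                         tolerance_mode = c("printed_precision", "absolute"),
                         absolute_tol = 0.1,
                         iph_proximity_tol = 5.0,
                         iph_override = NULL,
                         functional = NULL, basis = NULL,
                         catalog = media_catalog()) {
  tolerance_mode <- match.arg(tolerance_mode)
  stopifnot(printed_decimals >= 0, absolute_tol >= 0, iph_proximity_tol >= 0)
  structure(list(printed_decimals = printed_decimals,
                 tolerance_mode = tolerance_mode,
                 absolute_tol = absolute_tol,
                 iph_proximity_tol = iph_proximity_tol,
                 iph_override = iph_override,
                 functional = functional, basis = basis,
                 catalog = catalog),
            class = "audit_config")
}

# tolerance for a residual built from k independently rounded printed terms
.audit_tol <- function(cfg, k, unit) {
  if (cfg$tolerance_mode == "printed_precision")
    k * 0.5 * 10^(-cfg$printed_decimals)
  else
    as.numeric(convert_energy(cfg$absolute_tol, to = unit, from = "kJ/mol"))
}

.finding <- function(scope, row, molecule_id, site_id, check, residual, unit,
                     tolerance, verdict, diagnosis = "none",
                     medium = NA_character_) {
  data.frame(scope = scope, row = row,
             molecule_id = molecule_id %||% NA_character_,
             site_id = site_id %||% NA_character_,
             medium = medium %||% NA_character_,
             check = check, residual = residual, unit = unit,
             tolerance = tolerance, verdict = verdict, diagnosis = diagnosis,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# T1 residual and its rounded-term count for one row; NULL if indeterminate.
# prefer = "reported": a printed pathway total is the table's own claim of
# the pathway enthalpy, so it takes precedence over re-adding printed
# addends (addend/total mismatches surface as transcription findings);
# prefer = "components" re-adds the step descriptors when all four exist.
.t1_side <- function(total, is_reported, comp1, comp2, prefer) {
  have_total <- is.finite(total)
  have_comp <- is.finite(comp1) && is.finite(comp2)
  if (prefer == "components" && have_comp) list(v = comp1 + comp2, k = 2)
  else if (have_total)
    list(v = total, k = if (isTRUE(is_reported)) 1 else 2)
  else if (have_comp) list(v = comp1 + comp2, k = 2)
  else NULL
}
.t1_residual <- function(r, prefer = "reported") {
  s1 <- .t1_side(r$SETPT, r$SETPT_is_reported, r$IP, r$PDE, prefer)
  s2 <- .t1_side(r$SPLET, r$SPLET_is_reported, r$PA, r$ETE, prefer)
  if (is.null(s1) || is.null(s2)) return(NULL)
  list(res = s1$v - s2$v, k = s1$k + s2$k)
}

# per-row IP+PDE-BDE offset; prefers a reported BASE column, then
# components, then reported SETPT.  Returns value + rounded-term count.
.row_base <- function(r) {
  if (!is.null(r$BASE) && is.finite(r$BASE)) return(list(base = r$BASE, k = 1))
  if (!is.finite(r$BDE)) return(NULL)
  if (is.finite(r$IP) && is.finite(r$PDE))
    return(list(base = r$IP + r$PDE - r$BDE, k = 3))
  if (is.finite(r$SETPT))
    return(list(base = r$SETPT - r$BDE,
                k = if (isTRUE(r$SETPT_is_reported)) 2 else 3))
  NULL
}

#' Theorem-1 check: equality of the combined pathway sums
#'
#' Residual `(IP+PDE) - (PA+ETE)`, from components when all four step
#' descriptors are present (4 rounded terms), otherwise from the reported
#' sums (2 rounded terms).  Comparison is inclusive at the tolerance.
#'
#' @param d `descriptor_table`.
#' @param cfg `audit_config`.
#' @param prefer `"reported"` (default) takes a printed pathway total as
#'   that pathway's claimed enthalpy, falling back to re-added components;
#'   `"components"` re-adds the step descriptors whenever all four are
#'   present.  Mismatches between printed addends and printed totals are
#'   the transcription check's job, not T1's.
#' @return data.frame of findings, one row per table row.
#' @export
theorem1_check <- function(d, cfg = audit_config(),
                           prefer = c("reported", "components")) {
  prefer <- match.arg(prefer)
  d <- combined_sums(as_descriptor_table(d))
  out <- lapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    t1 <- .t1_residual(r, prefer)
    if (is.null(t1))
      return(.finding("row", i, r$molecule_id, r$site_id, "T1", NA_real_,
                      r$unit, NA_real_, "indeterminate", medium = r$medium))
    tol <- .audit_tol(cfg, t1$k, r$unit)
    .finding("row", i, r$molecule_id, r$site_id, "T1", t1$res, r$unit, tol,
             if (abs(t1$res) <= tol) "pass" else "fail", medium = r$medium)
  })
  do.call(rbind, out)
}

#' Theorem-2 site-invariance check (strict, reference-free)
#'
#' Computes the offset `r_i = (IP+PDE)_i - BDE_i` per row (using the
#' reported offset column `BASE` when the table carries one) and passes
#' iff `max |r_i - median(r)| <= tol`.  The reported residual is the
#' spread `max(r) - min(r)`.
#'
#' @inheritParams theorem1_check
#' @return One dataset-level finding.
#' @export
theorem2_site_invariance <- function(d, cfg = audit_config()) {
  d <- combined_sums(as_descriptor_table(d))
  bases <- lapply(seq_len(nrow(d)), function(i) .row_base(d[i, ]))
  ok <- !vapply(bases, is.null, TRUE)
  if (!any(ok))
    return(.finding("dataset", NA_integer_, NA, NA, "T2_site_invariance",
                    NA_real_, d$unit[1] %||% NA_character_, NA_real_,
                    "indeterminate", medium = d$medium[1]))
  r <- vapply(bases[ok], function(b) b$base, 0)
  k <- 2 * max(vapply(bases[ok], function(b) b$k, 0))
  tol <- .audit_tol(cfg, k, d$unit[1])
  dev <- max(abs(r - stats::median(r)))
  .finding("dataset", NA_integer_, NA, NA, "T2_site_invariance",
           max(r) - min(r), d$unit[1], tol,
           if (length(r) < 2 || dev <= tol) "pass" else "fail",
           medium = d$medium[1])
}

# resolve the IPH reference for one row, in the table's unit; NULL if none
.iph_reference <- function(r, cfg) {
  if (!is.null(cfg$iph_override)) return(cfg$iph_override)
  if (!is.null(r$IPH_ref) && is.finite(r$IPH_ref)) return(r$IPH_ref)
  if (!is.null(cfg$functional) && !is.null(cfg$basis) &&
      !is.na(r$medium) && tolower(r$medium) %in% tolower(cfg$catalog$media$name)) {
    val <- iph(cfg$functional, cfg$basis, r$medium, unit = "kJ/mol",
               catalog = cfg$catalog)
    return(as.numeric(convert_energy(val, r$unit)))
  }
  NULL
}

#' Theorem-2 reference check (loose)
#'
#' Residual `(IP+PDE) - BDE - IPH_ref` per row, compared against the
#' proximity tolerance (default 5 kJ/mol, converted to the table's unit).
#' The reference resolves in order: config override, per-row `IPH_ref`
#' column, catalog lookup for the declared medium and method.
#'
#' @inheritParams theorem1_check
#' @return data.frame of findings, one per row.
#' @export
theorem2_reference_check <- function(d, cfg = audit_config()) {
  d <- combined_sums(as_descriptor_table(d))
  out <- lapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    b <- .row_base(r)
    ref <- .iph_reference(r, cfg)
    if (is.null(b) || is.null(ref))
      return(.finding("row", i, r$molecule_id, r$site_id, "T2_reference",
                      NA_real_, r$unit, NA_real_, "indeterminate",
                      medium = r$medium))
    tol <- as.numeric(convert_energy(cfg$iph_proximity_tol, to = r$unit,
                                     from = "kJ/mol"))
    res <- b$base - ref
    .finding("row", i, r$molecule_id, r$site_id, "T2_reference", res, r$unit,
             tol, if (abs(res) <= tol) "pass" else "fail", medium = r$medium)
  })
  do.call(rbind, out)
}

#' Rank candidate media by closeness of an observed IP+PDE-BDE offset
#'
#' @param base_kj Observed offset, kJ/mol.
#' @param candidates data.frame with columns `medium` and `iph_kj`; built
#'   with [media_candidates()] or supplied directly (e.g. from a table's
#'   own printed reference values).
#' @return data.frame ranked by `deviation`, with attribute `matched`:
#'   the best medium is asserted only when its deviation is below half
#'   the smallest gap between candidate IPH values.
#' @export
infer_medium <- function(base_kj, candidates) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1,
            all(c("medium", "iph_kj") %in% names(candidates)))
  candidates$deviation <- abs(base_kj - candidates$iph_kj)
  out <- candidates[order(candidates$deviation), , drop = FALSE]
  rownames(out) <- NULL
  matched <- TRUE
  if (nrow(out) > 1) {
    gaps <- diff(sort(candidates$iph_kj))
    matched <- out$deviation[1] < min(gaps) / 2
  }
  attr(out, "matched") <- matched
  out
}

#' Candidate (medium, IPH) table for a method from the catalog
#' @param functional,basis Method key.
#' @param catalog A `media_catalog`.
#' @return data.frame with `medium`, `iph_kj`.
#' @export
media_candidates <- function(functional, basis, catalog = media_catalog()) {
  data.frame(
    medium = catalog$media$name,
    iph_kj = vapply(catalog$media$name, function(m)
      as.numeric(iph(functional, basis, m, catalog = catalog)), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

# does rescaling one side of the T1 residual by 4.184 (kcal<->kJ mix-up)
# bring it under tolerance?
.t1_unit_mixup <- function(r, tol) {
  s1 <- if (all(is.finite(c(r$IP, r$PDE)))) r$IP + r$PDE else r$SETPT
  s2 <- if (all(is.finite(c(r$PA, r$ETE)))) r$PA + r$ETE else r$SPLET
  if (!is.finite(s1) || !is.finite(s2)) return(FALSE)
  f <- energy_constants()$kcal_in_kJ
  any(abs(c(s1 * f - s2, s1 / f - s2, s1 - s2 * f, s1 - s2 / f)) <= tol)
}

#' Audit a full descriptor table
#'
#' Runs, per row: the T1 pathway-equality check, the ordering corollaries
#' (when all four step descriptors are present), the positivity bound
#' `BDE < IP+PDE`, a transcription cross-check of reported combined sums
#' against recomputed ones, and the loose T2 reference check.  Per
#' dataset: the strict T2 site-invariance check and medium inference on
#' the median IP+PDE-BDE offset.  Failing findings carry a diagnosis:
#' `unit_mixup_suspected`, `medium_mismatch_suspected` or
#' `gross_inconsistency`.
#'
#' @param d `descriptor_table` (or data.frame coercible to one).
#' @param cfg `audit_config`.
#' @param candidates Optional explicit medium-candidate table for
#'   inference (see [infer_medium()]); default builds from the catalog
#'   when `cfg` names a method.
#' @return Object of class `audit_report`: list with `findings`
#'   (data.frame), `inferred_medium` (or NA) and `n_rows`.
#' @export
audit_table <- function(d, cfg = audit_config(), candidates = NULL) {
  d <- combined_sums(as_descriptor_table(d))
  if (is.null(d$medium)) d$medium <- ""
  d$medium[is.na(d$medium)] <- ""
  unit <- d$unit[1] %||% "kJ/mol"
  findings <- theorem1_check(d, cfg)

  # ordering corollaries: one summary finding per row with all four steps
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    if (all(is.finite(c(r$IP, r$PA, r$PDE, r$ETE)))) {
      tie <- .audit_tol(cfg, 2, r$unit)
      cc <- corollary_orderings(r, tie_tol = tie)
      bad <- cc$check[cc$verdict == "violated"]
      findings <- rbind(findings, .finding(
        "row", i, r$molecule_id, r$site_id, "C1",
        residual = length(bad), unit = "count", tolerance = 0,
        verdict = if (length(bad)) "fail" else "pass", medium = r$medium))
    }
    b <- .row_base(r)
    if (!is.null(b)) {
      tol <- .audit_tol(cfg, b$k + 1, r$unit)
      findings <- rbind(findings, .finding(
        "row", i, r$molecule_id, r$site_id, "positivity", b$base, r$unit, tol,
        if (b$base > -tol) "pass" else "fail", medium = r$medium))
    }
    # transcription: reported sum vs recomputed sum
    for (side in c("SETPT", "SPLET")) {
      calc <- r[[paste0(side, "_calc")]]
      rep_ <- r[[side]]
      # a finding is only worth a row when the discrepancy exceeds
      # floating-point dust
      if (is.finite(calc) && is.finite(rep_) &&
          abs(rep_ - calc) > 1e-9 * max(1, abs(calc))) {
        tol <- .audit_tol(cfg, 3, r$unit)
        res <- rep_ - calc
        if (abs(res) > 0)
          findings <- rbind(findings, .finding(
            "row", i, r$molecule_id, r$site_id,
            paste0("transcription_", side), res, r$unit, tol,
            if (abs(res) <= tol) "pass" else "fail", medium = r$medium))
      }
    }
  }

  findings <- rbind(findings, theorem2_reference_check(d, cfg))

  # dataset-level checks run per declared medium: the T2 offset is only
  # constant within one medium
  if (is.null(candidates) && !is.null(cfg$functional) && !is.null(cfg$basis))
    candidates <- media_candidates(cfg$functional, cfg$basis, cfg$catalog)
  inferred <- character(0)
  for (med in unique(d$medium)) {
    grp <- d[d$medium == med, , drop = FALSE]
    findings <- rbind(findings, theorem2_site_invariance(grp, cfg))
    if (is.null(candidates)) next
    bases <- Filter(Negate(is.null),
                    lapply(seq_len(nrow(grp)), function(i) .row_base(grp[i, ])))
    if (!length(bases)) next
    base_kj <- as.numeric(convert_energy(
      stats::median(vapply(bases, function(b) b$base, 0)),
      to = "kJ/mol", from = unit))
    rank <- infer_medium(base_kj, candidates)
    best <- if (attr(rank, "matched")) rank$medium[1] else NA_character_
    inferred[med] <- best
    mismatch <- !is.na(best) && tolower(best) != tolower(med)
    findings <- rbind(findings, .finding(
      "dataset", NA_integer_, NA, NA, "medium_inference",
      rank$deviation[1], "kJ/mol", NA_real_,
      if (mismatch) "fail" else "pass",
      if (mismatch) "medium_mismatch_suspected" else "none", medium = med))
  }

  # diagnoses for failing row-level findings
  for (j in which(findings$verdict == "fail" & findings$scope == "row")) {
    i <- findings$row[j]
    r <- d[i, ]
    diag <- "gross_inconsistency"
    best <- inferred[r$medium %||% NA_character_] %||% NA_character_
    if (findings$check[j] == "T1" && .t1_unit_mixup(r, findings$tolerance[j]))
      diag <- "unit_mixup_suspected"
    else if (findings$check[j] %in% c("T2_reference", "positivity") &&
             !is.na(best) && tolower(best) != tolower(r$medium))
      diag <- "medium_mismatch_suspected"
    findings$diagnosis[j] <- diag
  }
  if (any(sel <- findings$check == "T2_site_invariance" &
                 findings$verdict == "fail"))
    findings$diagnosis[sel] <- "gross_inconsistency"

  rownames(findings) <- NULL
  structure(list(findings = findings, inferred_medium = inferred,
                 n_rows = nrow(d)),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  f <- x$findings
  cat("audit report:", x$n_rows, "rows,", nrow(f), "findings (",
      sum(f$verdict == "fail"), "fail /", sum(f$verdict == "pass"), "pass /",
      sum(f$verdict == "indeterminate"), "indeterminate )\n", sep = " ")
  inf <- x$inferred_medium[!is.na(x$inferred_medium)]
  if (length(inf))
    cat("inferred media:",
        paste(names(inf), "->", inf, collapse = "; "), "\n")
  fails <- f[f$verdict == "fail", ]
  if (nrow(fails)) {
    cat("failures:\n")
    print(fails[, c("scope", "row", "molecule_id", "site_id", "medium",
                    "check", "residual", "unit", "tolerance", "diagnosis")],
          row.names = FALSE)
  }
  invisible(x)
}
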
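# fixed van der Waals radii (Angstrom); hydrogens are ignored entirely
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
VDW_DEFAULT <- 1.8

#' Read protein coordinates from a PDB-format file
#'
#' Parses `ATOM` records (fixed-column PDB format). HETATM records, waters,
#' hydrogens and alternate locations other than blank/`A` are skipped.
#' Residue numbering follows the coordinate file's author numbering.
#'
#' @param path path to a PDB-format text file.
#' @return a `structure_model`: data.frame with columns `chain`, `resseq`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `radius`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM")]
  if (!length(lines)) stop("no ATOM records in ", path)
  fx <- function(from, to) trimws(substring(lines, from, to))
  altloc <- fx(17, 17)
  element <- fx(77, 78)
  name <- fx(13, 16)
  # fall back to the first letter of the atom name when the element
  # column is absent
  element <- ifelse(nzchar(element), element, substring(gsub("[0-9]", "", name), 1, 1))
  element <- toupper(element)
  keep <- altloc %in% c("", "A") & element != "H" & element != "D"
  model <- data.frame(
    chain = fx(22, 22)[keep], resseq = as.integer(fx(23, 26)[keep]),
    resname = fx(18, 20)[keep], atom = name[keep], element = element[keep],
    x = as.numeric(fx(31, 38)[keep]), y = as.numeric(fx(39, 46)[keep]),
    z = as.numeric(fx(47, 54)[keep]), stringsAsFactors = FALSE)
  if (anyNA(model$x) || anyNA(model$y) || anyNA(model$z))
    stop("malformed coordinates in ", path)
  model$radius <- unname(ifelse(model$element %in% names(VDW_RADII),
                                VDW_RADII[model$element], VDW_DEFAULT))
  class(model) <- c("structure_model", "data.frame")
  model
}

#' Construct a structure model from atom coordinates
#'
#' Programmatic counterpart of [read_pdb()], mainly for building synthetic
#' test structures.
#'
#' @param chain,resseq,x,y,z vectors of equal length.
#' @param element atom element symbols (sets the van der Waals radius).
#' @param resname,atom optional labels.
#' @return a `structure_model` data.frame.
#' @export
structure_model <- function(chain, resseq, x, y, z, element = "C",
                            resname = "ALA", atom = "CA") {
  n <- length(x)
  model <- data.frame(chain = rep_len(chain, n),
                      resseq = rep_len(as.integer(resseq), n),
                      resname = rep_len(resname, n),
                      atom = rep_len(atom, n),
                      element = rep_len(toupper(element), n),
                      x = x, y = y, z = z, stringsAsFactors = FALSE)
  if (any(!is.finite(c(x, y, z)))) stop("non-finite coordinates")
  model$radius <- unname(ifelse(model$element %in% names(VDW_RADII),
                                VDW_RADII[model$element], VDW_DEFAULT))
  class(model) <- c("structure_model", "data.frame")
  model
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
unit_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Per atom, the fraction of `n_points` quasi-uniform sphere points at
#' radius r_vdw + probe that fall inside no neighbouring atom's expanded
#' sphere, times the expanded sphere area 4 pi (r_vdw + probe)^2; residue
#' ASA is the sum over its atoms. The point set is deterministic, so
#' results are exactly reproducible. The probe models a water molecule
#' (radius 1.4 Angstrom, the universal SASA convention).
#'
#' @param model a `structure_model` (see [read_pdb()]).
#' @param probe_radius probe radius in Angstrom.
#' @param n_points number of quadrature points per atom.
#' @return data.frame with columns `chain`, `resseq`, `asa` (Angstrom^2).
#' @export
calc_sasa <- function(model, probe_radius = 1.4, n_points = 960L) {
  if (nrow(model) == 0) stop("structure model has no atoms")
  xyz <- as.matrix(model[, c("x", "y", "z")])
  R <- model$radius + probe_radius
  pts <- unit_sphere_points(n_points)
  n <- nrow(model)
  asa_atom <- numeric(n)
  for (i in seq_len(n)) {
    di <- xyz[, 1] - xyz[i, 1]
    d2 <- di * di
    di <- xyz[, 2] - xyz[i, 2]
    d2 <- d2 + di * di
    di <- xyz[, 3] - xyz[i, 3]
    d2 <- d2 + di * di
    nb <- which(d2 < (R[i] + R)^2 & d2 > 0)
    sp <- pts * R[i]
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      accessible <- accessible & dd >= R[j]^2
      if (!any(accessible)) break
    }
    asa_atom[i] <- mean(accessible) * 4 * pi * R[i]^2
  }
  res <- rowsum(asa_atom, paste(model$chain, model$resseq, sep = ":"))
  key <- unique(data.frame(chain = model$chain, resseq = model$resseq,
                           stringsAsFactors = FALSE))
  key$asa <- res[paste(key$chain, key$resseq, sep = ":"), 1]
  rownames(key) <- NULL
  key
}

#' Identify interface residues of a chain pair
#'
#' Computes per-residue ASA for each chain alone (unbound) and within the
#' two-chain complex; the burial on binding is
#' `delta_asa = ASA_unbound - ASA_complex`. Residues burying more than
#' 1 Angstrom^2 are interface residues (strict inequality).
#'
#' @param model `structure_model` containing both chains.
#' @param chain_pair character vector of two chain identifiers.
#' @param probe_radius,n_points passed to [calc_sasa()].
#' @param delta_cutoff burial threshold in Angstrom^2.
#' @return `interface_annotation` data.frame: `chain`, `resseq`,
#'   `asa_unbound`, `asa_complex`, `delta_asa`, `is_interface`; the chain
#'   pair is kept in attribute `chain_pair`.
#' @export
interface_residues <- function(model, chain_pair, probe_radius = 1.4,
                               n_points = 960L, delta_cutoff = 1.0) {
  stopifnot(length(chain_pair) == 2)
  missing <- setdiff(chain_pair, unique(model$chain))
  if (length(missing))
    stop("chain(s) absent from structure: ", paste(missing, collapse = ", "))
  both <- model[model$chain %in% chain_pair, ]
  complex_asa <- calc_sasa(both, probe_radius, n_points)
  unbound <- do.call(rbind, lapply(chain_pair, function(ch)
    calc_sasa(model[model$chain == ch, ], probe_radius, n_points)))
  key_c <- paste(complex_asa$chain, complex_asa$resseq)
  key_u <- paste(unbound$chain, unbound$resseq)
  out <- unbound[, c("chain", "resseq")]
  out$asa_unbound <- unbound$asa
  out$asa_complex <- complex_asa$asa[match(key_u, key_c)]
  out$delta_asa <- out$asa_unbound - out$asa_complex
  out$is_interface <- out$delta_asa > delta_cutoff
  rownames(out) <- NULL
  attr(out, "chain_pair") <- chain_pair
  class(out) <- c("interface_annotation", "data.frame")
  out
}

#' Flag interface domain pairs
#'
#' A (domain on chain A, domain on chain B) pair is an interface-domain
#' pair when either (criterion 1) the domain pair is a known
#' domain-domain interaction (3did/iPfam-style table) and each domain
#' contains at least one interface residue, or (criterion 2) each domain
#' contains 5 or more interface residues.
#'
#' @param annotation result of [interface_residues()].
#' @param domain_ranges data.frame with columns `chain`, `domain_id`,
#'   `start`, `end` (author residue numbering; ranges on a chain must not
#'   overlap).
#' @param known_ddi optional data.frame of known interacting domain pairs
#'   with columns `domain_a`, `domain_b` (unordered).
#' @param min_residues criterion-2 threshold.
#' @return data.frame of domain pairs: `domain_a`, `chain_a`, `domain_b`,
#'   `chain_b`, `n_ifres_a`, `n_ifres_b`, `is_interface_domain`,
#'   `criterion` (1, 2 or NA).
#' @export
interface_domains <- function(annotation, domain_ranges, known_ddi = NULL,
                              min_residues = 5L) {
  chains <- attr(annotation, "chain_pair") %||% unique(annotation$chain)
  stopifnot(length(chains) == 2)
  for (ch in unique(domain_ranges$chain)) {
    d <- domain_ranges[domain_ranges$chain == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping domain ranges on chain ", ch)
  }
  n_ifres <- function(ch, start, end)
    sum(annotation$is_interface & annotation$chain == ch &
          annotation$resseq >= start & annotation$resseq <= end)
  da <- domain_ranges[domain_ranges$chain == chains[[1]], ]
  db <- domain_ranges[domain_ranges$chain == chains[[2]], ]
  if (!nrow(da) || !nrow(db))
    return(data.frame(domain_a = character(), chain_a = character(),
                      domain_b = character(), chain_b = character(),
                      n_ifres_a = integer(), n_ifres_b = integer(),
                      is_interface_domain = logical(), criterion = integer(),
                      stringsAsFactors = FALSE))
  known <- character(0)
  if (!is.null(known_ddi) && nrow(known_ddi))
    known <- c(paste(known_ddi$domain_a, known_ddi$domain_b),
               paste(known_ddi$domain_b, known_ddi$domain_a))
  grid <- expand.grid(ia = seq_len(nrow(da)), ib = seq_len(nrow(db)))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    A <- da[grid$ia[r], ]
    B <- db[grid$ib[r], ]
    na <- n_ifres(A$chain, A$start, A$end)
    nb <- n_ifres(B$chain, B$start, B$end)
    crit1 <- paste(A$domain_id, B$domain_id) %in% known && na >= 1 && nb >= 1
    crit2 <- na >= min_residues && nb >= min_residues
    data.frame(domain_a = A$domain_id, chain_a = A$chain,
               domain_b = B$domain_id, chain_b = B$chain,
               n_ifres_a = na, n_ifres_b = nb,
               is_interface_domain = crit1 || crit2,
               criterion = if (crit1) 1L else if (crit2) 2L else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify the structural locus of mutations
#'
#' Each mutated residue is classified, in order of precedence, as
#' `interface_residue` (buried on binding), `interface_domain` (inside a
#' flagged interface domain but not itself at the interface) or `away`.
#' Residues not resolved in the structure are classified `unmapped` and
#' should be excluded from cohort statistics.
#'
#' @param mutations data.frame with columns `chain`, `resseq` (plus any
#'   identifier columns, which are carried through).
#' @param annotation result of [interface_residues()].
#' @param domain_flags result of [interface_domains()].
#' @param domain_ranges the domain range table used for `domain_flags`.
#' @return the `mutations` data.frame with an added `locus_class` column.
#' @export
classify_locus <- function(mutations, annotation, domain_flags,
                           domain_ranges) {
  flagged <- unique(c(
    paste(domain_flags$chain_a, domain_flags$domain_a)[
      domain_flags$is_interface_domain],
    paste(domain_flags$chain_b, domain_flags$domain_b)[
      domain_flags$is_interface_domain]))
  cls <- vapply(seq_len(nrow(mutations)), function(i) {
    ch <- mutations$chain[i]
    rs <- mutations$resseq[i]
    row <- annotation[annotation$chain == ch & annotation$resseq == rs, ]
    if (!nrow(row)) return("unmapped")
    if (row$is_interface[[1]]) return("interface_residue")
    dom <- domain_ranges[domain_ranges$chain == ch &
                           domain_ranges$start <= rs &
                           domain_ranges$end >= rs, ]
    if (nrow(dom) && any(paste(dom$chain, dom$domain_id) %in% flagged))
      return("interface_domain")
    "away"
  }, character(1))
  mutations$locus_class <- cls
  mutations
}
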
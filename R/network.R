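#' @useDynLib erkltp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames coef lm anova predict approx sd
#' @importFrom stats fitted resid vcov median
#' @importFrom utils read.delim write.table head
NULL

# ---- reaction-side parsing -------------------------------------------------

# "A + B", "2 A", "A + A", "" / "0" -> named integer multiset
.parse_side <- function(side) {
  side <- trimws(side)
  if (is.na(side) || side == "" || side == "0") return(integer(0))
  parts <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  out <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]+)\\s+(.*)$", p))[[1]]
    if (length(m) == 3) {
      n <- as.integer(m[2]); nm <- m[3]
    } else {
      n <- 1L; nm <- p
    }
    out[nm] <- if (nm %in% names(out)) out[[nm]] + n else n
  }
  out
}

.format_side <- function(multiset) {
  if (length(multiset) == 0) return("")
  paste(ifelse(multiset > 1, paste(multiset, names(multiset)), names(multiset)),
        collapse = " + ")
}

# ---- constructor -----------------------------------------------------------

#' Construct a mass-action reaction network
#'
#' The container for the signalling model: a species table (name, initial
#' concentration in nM, role tag) and a reaction table (label, reactant and
#' product multisets, forward and optional reverse rate constants), together
#' with a well-mixed compartment volume. Bimolecular rate constants are in
#' /nM/s, unimolecular in /s, zeroth-order (source) in nM/s.
#'
#' @param species data frame with columns `name`, `initial_nM` (or
#'   `concentration_nM`), and optionally `role` (one of input, kinase,
#'   phosphatase, gtpase, gef, gap, buffer, pump, other).
#' @param reactions data frame with columns `label`, `reactants`, `products`
#'   (sides written e.g. `"A + B"`, `"2 A"`, or `""` for nothing), `kf`, and
#'   optionally `kr` (NA or absent for irreversible reactions).
#' @param volume compartment volume in um^3 (default 4, a dendrite-scale
#'   compartment; spine-sized volumes are 0.1-0.8).
#' @param parameterization `"fixture"` or `"published"`; experiment suites that
#'   compare against published quantities refuse fixture networks.
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, volume = 4,
                             parameterization = "fixture") {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!"initial_nM" %in% names(species)) {
    if ("concentration_nM" %in% names(species))
      species$initial_nM <- species$concentration_nM
    else stop("species table needs an 'initial_nM' (or 'concentration_nM') column")
  }
  if (!"role" %in% names(species)) species$role <- "other"
  roles <- c("input", "kinase", "phosphatase", "gtpase", "gef", "gap",
             "buffer", "pump", "other")
  if (!all(species$role %in% roles))
    stop("unknown role tag(s): ", paste(setdiff(species$role, roles), collapse = ", "))
  if (anyDuplicated(species$name))
    stop("duplicate species names: ",
         paste(unique(species$name[duplicated(species$name)]), collapse = ", "))
  if (any(species$initial_nM < 0)) stop("initial concentrations must be >= 0")
  needed <- c("label", "reactants", "products", "kf")
  if (!all(needed %in% names(reactions)))
    stop("reaction table needs columns: ", paste(needed, collapse = ", "))
  if (!"kr" %in% names(reactions)) reactions$kr <- NA_real_
  species$initial_nM <- as.numeric(species$initial_nM)
  reactions$kf <- as.numeric(reactions$kf)
  reactions$kr <- as.numeric(reactions$kr)
  if (any(reactions$kf < 0, na.rm = TRUE) || any(reactions$kr < 0, na.rm = TRUE))
    stop("rate constants must be >= 0")
  for (i in seq_len(nrow(reactions))) {
    for (col in c("reactants", "products")) {
      side <- .parse_side(reactions[[col]][i])
      if (sum(side) > 2)
        stop("reaction '", reactions$label[i], "': stoichiometric order > 2 on one side")
      unknown <- setdiff(names(side), species$name)
      if (length(unknown))
        stop("reaction '", reactions$label[i], "' (row ", i, ") references ",
             "undeclared species: ", paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(species = species[, c("name", "initial_nM", "role")],
         reactions = reactions[, c("label", "reactants", "products", "kf", "kr")],
         volume = volume),
    class = "reaction_network", parameterization = parameterization)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions, volume ", x$volume, " um^3 (",
      attr(x, "parameterization"), " parameterization)\n", sep = "")
  invisible(x)
}

# ---- file IO ---------------------------------------------------------------

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load a reaction network from parameter tables
#'
#' Reads one species table and one or more reaction tables (UTF-8 TSV or CSV,
#' one row per reaction) and returns a validated network. The loaded network
#' keeps exactly one reaction row per input row across all reaction files.
#'
#' @param species_file path to the species table (`name`,
#'   `concentration_nM`/`initial_nM`, optional `role`).
#' @param reaction_files character vector of reaction-table paths
#'   (`label`, `reactants`, `products`, `kf`, optional `kr`).
#' @param volume compartment volume in um^3.
#' @param parameterization see [reaction_network()].
#' @return a `reaction_network`.
#' @export
load_network <- function(species_file, reaction_files, volume = 4,
                         parameterization = "published") {
  species <- .read_table_auto(species_file)
  reactions <- do.call(rbind, lapply(reaction_files, .read_table_auto))
  reaction_network(species, reactions, volume = volume,
                   parameterization = parameterization)
}

#' Serialize a network back to parameter tables
#'
#' Writes the species and reaction tables as tab-separated text with full
#' numeric precision, so that loading then serializing round-trips.
#'
#' @param net a `reaction_network`.
#' @param species_file,reactions_file output paths.
#' @export
write_network_tables <- function(net, species_file, reactions_file) {
  sp <- net$species
  sp$initial_nM <- vapply(sp$initial_nM, function(v) format(v, digits = 17), "")
  rx <- net$reactions
  rx$kf <- vapply(rx$kf, function(v) format(v, digits = 17), "")
  rx$kr <- vapply(rx$kr, function(v) if (is.na(v)) "NA" else format(v, digits = 17), "")
  write.table(sp, species_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rx, reactions_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(species_file, reactions_file))
}

# ---- knockouts -------------------------------------------------------------

#' Describe a knockout / variant configuration
#'
#' Encodes the model variants used throughout: zeroing labeled rate constants
#' (pathway blocks such as `K_CK`, `K_Syn1`..`K_Syn3`, `K_Epac`, `K_PKA`),
#' removing species (Ras/Rap1/Raf knockouts), scaling initial quantities
#' (e.g. doubling Rap1), and switching off Raf dimerization or phospho-SynGap
#' dispersion.
#'
#' @param zero_rates character vector of reaction labels whose `kf`/`kr` are
#'   set to zero.
#' @param remove_species character vector of species whose initial amount is
#'   set to zero.
#' @param scale_quantities named numeric vector of positive multipliers
#'   applied to initial amounts.
#' @param dimerization if `FALSE`, reactions labeled `K_dimer` are zeroed and
#'   any monomeric-bypass reaction labeled `K_cat_mono` receives the catalytic
#'   rate of reactions labeled `K_cat_dimer` (the monomeric Raf complex is
#'   granted the dimer's activity).
#' @param dispersion if `FALSE`, reactions labeled `K_Syn3` (conversion of
#'   phospho-SynGap to its dendrite-dispersed, GAP-inactive form) are zeroed.
#' @return an object of class `knockout_config`.
#' @export
knockout_config <- function(zero_rates = character(), remove_species = character(),
                            scale_quantities = numeric(), dimerization = TRUE,
                            dispersion = TRUE) {
  if (length(scale_quantities) && (is.null(names(scale_quantities)) ||
      any(!nzchar(names(scale_quantities)))))
    stop("scale_quantities must be a named vector")
  if (any(scale_quantities <= 0)) stop("quantity multipliers must be > 0")
  structure(list(zero_rates = unique(zero_rates),
                 remove_species = unique(remove_species),
                 scale_quantities = scale_quantities,
                 dimerization = isTRUE(dimerization),
                 dispersion = isTRUE(dispersion)),
            class = "knockout_config")
}

#' Apply a knockout configuration to a network
#'
#' Returns a modified copy; the input network is never touched. Zeroed labels
#' get `kf = kr = 0`, removed species get initial amount 0, multipliers scale
#' initial amounts. Applying the same configuration twice is a no-op beyond
#' the first application for rate zeroing and removal (idempotent), and
#' configurations touching disjoint labels/species commute.
#'
#' @param net a `reaction_network`.
#' @param ko a [knockout_config()].
#' @return a new `reaction_network`.
#' @export
apply_knockout <- function(net, ko) {
  stopifnot(inherits(net, "reaction_network"), inherits(ko, "knockout_config"))
  bad <- setdiff(ko$zero_rates, net$reactions$label)
  if (length(bad))
    stop("unknown reaction label(s): ", paste(bad, collapse = ", "),
         "; valid labels: ", paste(unique(net$reactions$label), collapse = ", "))
  bad <- setdiff(c(ko$remove_species, names(ko$scale_quantities)), net$species$name)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  out <- net
  hit <- out$reactions$label %in% ko$zero_rates
  out$reactions$kf[hit] <- 0
  out$reactions$kr[hit & !is.na(out$reactions$kr)] <- 0
  out$species$initial_nM[out$species$name %in% ko$remove_species] <- 0
  if (length(ko$scale_quantities)) {
    idx <- match(names(ko$scale_quantities), out$species$name)
    out$species$initial_nM[idx] <- out$species$initial_nM[idx] * ko$scale_quantities
  }
  if (!ko$dispersion) {
    hit <- out$reactions$label == "K_Syn3"
    out$reactions$kf[hit] <- 0
    out$reactions$kr[hit & !is.na(out$reactions$kr)] <- 0
  }
  if (!ko$dimerization) {
    hit <- out$reactions$label == "K_dimer"
    out$reactions$kf[hit] <- 0
    out$reactions$kr[hit & !is.na(out$reactions$kr)] <- 0
    dimcat <- out$reactions$kf[out$reactions$label == "K_cat_dimer"]
    if (length(dimcat))
      out$reactions$kf[out$reactions$label == "K_cat_mono"] <- dimcat[1]
  }
  out
}

# ---- stoichiometry and validation -----------------------------------------

# expand reversible reactions to an irreversible list (internal)
.expand_reactions <- function(net) {
  sp <- net$species$name
  rows <- list()
  for (i in seq_len(nrow(net$reactions))) {
    r <- net$reactions[i, ]
    re <- .parse_side(r$reactants); pr <- .parse_side(r$products)
    rows[[length(rows) + 1L]] <- list(label = r$label, reactants = re,
                                      products = pr, k = r$kf)
    if (!is.na(r$kr))
      rows[[length(rows) + 1L]] <- list(label = r$label, reactants = pr,
                                        products = re, k = r$kr)
  }
  rows
}

# reactant / net stoichiometry matrices over the irreversible expansion
.stoich <- function(net) {
  sp <- net$species$name
  rows <- .expand_reactions(net)
  nr <- length(rows); ns <- length(sp)
  RS <- matrix(0L, nr, ns, dimnames = list(NULL, sp))
  NS <- matrix(0L, nr, ns, dimnames = list(NULL, sp))
  k <- numeric(nr); labels <- character(nr)
  for (j in seq_len(nr)) {
    r <- rows[[j]]
    RS[j, names(r$reactants)] <- as.integer(r$reactants)
    NS[j, names(r$products)] <- NS[j, names(r$products), drop = TRUE] +
      as.integer(r$products)
    NS[j, names(r$reactants)] <- NS[j, names(r$reactants), drop = TRUE] -
      as.integer(r$reactants)
    k[j] <- r$k; labels[j] <- r$label
  }
  list(RS = RS, NS = NS, k = k, labels = labels, species = sp)
}

#' Net stoichiometry matrix
#'
#' Species-by-reaction net stoichiometry over the irreversible expansion of
#' the network (a reversible reaction contributes two columns).
#'
#' @param net a `reaction_network`.
#' @return integer matrix, species in rows.
#' @export
stoichiometry_matrix <- function(net) {
  st <- .stoich(net)
  t(st$NS)
}

#' Conserved moieties of a network
#'
#' Computes a basis of the left null space of the net stoichiometry matrix:
#' linear combinations of species amounts that are invariant under every
#' reaction (e.g. total ERK across its phosphoforms, total CaMKII). Basis
#' vectors are rescaled to small integers where possible.
#'
#' @param net a `reaction_network`.
#' @param tol singular-value tolerance.
#' @return numeric matrix, one column per conserved combination, rows named by
#'   species; zero columns if nothing is conserved.
#' @export
conserved_moieties <- function(net, tol = 1e-9) {
  S <- stoichiometry_matrix(net)          # ns x nr
  ns <- nrow(S)
  sv <- svd(S, nu = ns)
  r <- sum(sv$d > tol * max(sv$d, 1))
  if (r >= ns) {
    return(matrix(numeric(0), ns, 0, dimnames = list(rownames(S), NULL)))
  }
  W <- sv$u[, seq.int(r + 1L, ns), drop = FALSE]   # t(S) %*% w = 0
  W <- apply(W, 2, function(w) {
    w[abs(w) < tol] <- 0
    nz <- abs(w[w != 0])
    if (!length(nz)) return(w)
    w <- w / min(nz)
    wi <- round(w)
    if (max(abs(w - wi)) < 1e-6 && max(abs(wi)) <= 64) wi else w
  })
  W <- as.matrix(W)
  rownames(W) <- rownames(S)
  W
}

#' Validate a network's structure
#'
#' Reports conserved moieties (from the stoichiometry null space), species not
#' referenced by any reaction, and reactions whose rates are all zero. If
#' `expected_moieties` is given (a list of character vectors of species names,
#' each expected to have a conserved total), each is checked against the
#' stoichiometry and violations are flagged.
#'
#' @param net a `reaction_network`.
#' @param expected_moieties optional list of species-name vectors.
#' @return an object of class `network_validation`.
#' @export
validate_network <- function(net, expected_moieties = NULL) {
  st <- .stoich(net)
  moieties <- conserved_moieties(net)
  used <- colnames(st$RS)[colSums(abs(st$RS)) + colSums(abs(st$NS)) > 0]
  dangling <- setdiff(net$species$name, used)
  zr <- net$reactions$label[net$reactions$kf == 0 &
                              (is.na(net$reactions$kr) | net$reactions$kr == 0)]
  violations <- character(0)
  if (!is.null(expected_moieties)) {
    S <- t(st$NS)
    for (m in expected_moieties) {
      w <- as.numeric(net$species$name %in% m)
      if (any(abs(crossprod(S, w)) > 1e-9))
        violations <- c(violations, paste(m, collapse = " + "))
    }
  }
  structure(list(moieties = moieties, dangling_species = dangling,
                 zero_rate_reactions = zr,
                 conservation_violations = violations,
                 ok = length(violations) == 0),
            class = "network_validation")
}

#' @export
print.network_validation <- function(x, ...) {
  cat("<network_validation>\n")
  cat("  conserved moieties:", ncol(x$moieties), "\n")
  for (j in seq_len(ncol(x$moieties))) {
    w <- x$moieties[, j]
    cat("   ", .format_side(setNames(w[w != 0], names(w[w != 0]))), "\n")
  }
  cat("  dangling species:",
      if (length(x$dangling_species)) paste(x$dangling_species, collapse = ", ") else "none", "\n")
  cat("  zero-rate reactions:",
      if (length(x$zero_rate_reactions)) paste(x$zero_rate_reactions, collapse = ", ") else "none", "\n")
  if (length(x$conservation_violations))
    cat("  CONSERVATION VIOLATIONS:",
        paste(x$conservation_violations, collapse = "; "), "\n")
  invisible(x)
}
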
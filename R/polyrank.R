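#' Packaged binding-site residue lists
#'
#' The local-anesthetic binding-site residues of the three target channels:
#' TASK-1 lateral fenestration (chains A, B), Nav1.5 domain III/IV site,
#' and Kv1.5 central cavity (CC) and side pockets (SP).
#'
#' @param channel Optional channel filter ("TASK-1", "NaV1.5", "KV1.5").
#' @param site Optional site filter.
#' @return data.frame: channel, site, chain, aa, resno.
#' @export
binding_sites <- function(channel = NULL, site = NULL) {
  path <- system.file("extdata", "binding_sites.json", package = "afsilico")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tabs <- lapply(seq_len(nrow(raw$sites)), function(i) {
    res <- raw$sites$residues[[i]]
    cbind(data.frame(channel = raw$sites$channel[i],
                     site = raw$sites$site[i]), res)
  })
  out <- do.call(rbind, tabs)
  if (!is.null(channel)) out <- out[out$channel == channel, ]
  if (!is.null(site)) out <- out[out$site == site, ]
  if (nrow(out) == 0) stop("no such binding site")
  if (anyDuplicated(out[c("channel", "site", "chain", "resno")])) {
    stop("duplicate residues in binding-site table")
  }
  rownames(out) <- NULL
  out
}

#' Count binding-site residues contacted by a docked ligand
#'
#' Number of distinct site residues having at least one heavy atom within
#' `cutoff` of at least one ligand heavy atom (hydrogens ignored). The
#' ligand is identified as the HETATM records of the structure (excluding
#' water), the receptor as the ATOM records.
#'
#' @param pdb_path Path to a pose PDB (receptor ATOM + ligand HETATM).
#' @param site Binding-site data.frame from [binding_sites()] (columns
#'   chain, resno).
#' @param cutoff Contact distance (Angstrom).
#' @return Integer contact count, between 0 and `nrow(site)`.
#' @export
count_contacts <- function(pdb_path, site, cutoff = 5.0) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("count_contacts requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(pdb_path)
  atoms <- pdb$atom
  heavy <- !(atoms$elesy %in% "H") &
    !grepl("^[0-9]*H", trimws(atoms$elety))
  lig <- atoms$type == "HETATM" & !(atoms$resid %in% c("HOH", "WAT")) & heavy
  if (!any(lig)) stop("no ligand heavy atoms (HETATM) in ", pdb_path)
  lx <- as.matrix(atoms[lig, c("x", "y", "z")])
  n <- 0L
  for (i in seq_len(nrow(site))) {
    sel <- atoms$type == "ATOM" & atoms$chain == site$chain[i] &
      atoms$resno == site$resno[i] & heavy
    if (!any(sel)) {
      stop(sprintf("binding-site residue %s:%d not found in structure",
                   site$chain[i], site$resno[i]))
    }
    rx <- as.matrix(atoms[sel, c("x", "y", "z")])
    d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * rx %*% t(lx)
    if (min(d2) <= cutoff^2) n <- n + 1L
  }
  n
}

#' Score docking poses within one (channel, site) set
#'
#' Min-max normalization of binding free energy (more negative energy
#' closer to 1) and binding-site contact count (more contacts closer to
#' 1), combined as their average:
#' `dgbind_norm = (max dG - dG) / (max dG - min dG)`,
#' `int_norm = (n - min n) / (max n - min n)`,
#' `normt = (dgbind_norm + int_norm) / 2`.
#' A degenerate column (min = max) normalizes to all 1.0.
#'
#' @param poses data.frame with columns compound, pose_id, dg_bind,
#'   n_contacts (one channel/site).
#' @return The input with dgbind_norm, int_norm, normt columns appended.
#' @export
score_poses <- function(poses) {
  if (nrow(poses) == 0) stop("empty pose set")
  minmax_hi_good <- function(x) {
    if (max(x) == min(x)) return(rep(1.0, length(x)))
    (x - min(x)) / (max(x) - min(x))
  }
  minmax_lo_good <- function(x) {
    if (max(x) == min(x)) return(rep(1.0, length(x)))
    (max(x) - x) / (max(x) - min(x))
  }
  poses$dgbind_norm <- minmax_lo_good(poses$dg_bind)
  poses$int_norm <- minmax_hi_good(poses$n_contacts)
  poses$normt <- (poses$dgbind_norm + poses$int_norm) / 2
  poses
}

#' Order poses and select the best pose per compound
#'
#' Poses are sorted by int_norm (descending), then normt (descending),
#' then binding energy (ascending), then pose id - a deterministic total
#' order prioritizing binding-site contacts over energy. The first pose
#' of each compound in that order is its best pose; compounds are ordered
#' by their best pose's position.
#'
#' @param scored Output of [score_poses()].
#' @return List with `ordering` (compound ids, best first) and
#'   `best_poses` (one row per compound, in order).
#' @export
rank_and_select <- function(scored) {
  o <- order(-scored$int_norm, -scored$normt, scored$dg_bind,
             as.character(scored$pose_id))
  sorted <- scored[o, ]
  best <- sorted[!duplicated(sorted$compound), ]
  rownames(best) <- NULL
  list(ordering = as.character(best$compound), best_poses = best)
}

#' Per-channel compound RANK from one or more site orderings
#'
#' For a single-site channel the RANK is the ordinal position (1 = best).
#' For a multi-site channel (Kv1.5 CC + SP) each compound takes its best
#' (minimum) ordinal across sites - compounds absent from a site are
#' imputed worst-rank-plus-one there - and ranks are then re-densified to
#' 1..n (ties broken by compound id).
#'
#' @param site_orderings List of character vectors (compound ids, best
#'   first), one per site.
#' @return Named integer vector: compound -> RANK.
#' @export
rank_channel <- function(site_orderings) {
  if (length(site_orderings) == 0) stop("need at least one site ordering")
  compounds <- sort(unique(unlist(site_orderings)))
  ords <- sapply(site_orderings, function(ord) {
    pos <- match(compounds, ord)
    pos[is.na(pos)] <- length(ord) + 1L
    pos
  })
  if (is.null(dim(ords))) ords <- matrix(ords, ncol = length(site_orderings))
  best <- apply(ords, 1, min)
  o <- order(best, compounds)
  rank <- integer(length(compounds))
  rank[o] <- seq_along(compounds)
  names(rank) <- compounds
  rank
}

#' GLOBAL RANK across channels
#'
#' Sums each compound's per-channel RANK; compounds are ordered by the
#' sum (ascending), ties broken by the best single-channel RANK, then by
#' compound id.
#'
#' @param channel_ranks Named list of per-channel RANK vectors (from
#'   [rank_channel()]), identical compound universes.
#' @return data.frame: compound, one RANK column per channel,
#'   global_rank, position.
#' @export
rank_global <- function(channel_ranks) {
  if (length(channel_ranks) == 0) stop("no channel rank tables")
  universe <- sort(names(channel_ranks[[1]]))
  for (cr in channel_ranks) {
    if (!identical(sort(names(cr)), universe)) {
      stop("inconsistent compound universes across channels")
    }
  }
  m <- sapply(channel_ranks, function(cr) cr[universe])
  if (is.null(dim(m))) m <- matrix(m, ncol = length(channel_ranks),
                                   dimnames = list(universe, names(channel_ranks)))
  global <- rowSums(m)
  best_single <- apply(m, 1, min)
  o <- order(global, best_single, universe)
  out <- data.frame(compound = universe, m, global_rank = global,
                    row.names = NULL, check.names = FALSE)
  out <- out[o, ]
  out$position <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full polypharmacology ranking pipeline
#'
#' Scores poses per (channel, site), selects each compound's best pose,
#' derives per-channel RANKs (multi-site channels combined best-of-sites)
#' and the cross-channel GLOBAL RANK.
#'
#' @param poses data.frame with columns compound, channel, site, pose_id,
#'   dg_bind and either n_contacts or pdb_path (contacts are then counted
#'   against the packaged binding sites with [count_contacts()]).
#' @param sites Binding-site table (defaults to [binding_sites()]).
#' @param cutoff Contact cutoff (Angstrom) when counting from structures.
#' @return List with `scored` (all scored poses), `channel_ranks`, and
#'   `global` (the final rank table).
#' @export
rank_compounds <- function(poses, sites = binding_sites(), cutoff = 5.0) {
  if (is.null(poses$n_contacts)) poses$n_contacts <- NA_real_
  need <- !is.finite(poses$n_contacts)
  if (any(need)) {
    if (is.null(poses$pdb_path)) {
      stop("poses need either n_contacts or pdb_path")
    }
    for (i in which(need)) {
      st <- sites[sites$channel == poses$channel[i] &
                    sites$site == poses$site[i], ]
      if (nrow(st) == 0) {
        stop("no binding-site definition for ", poses$channel[i], "/",
             poses$site[i])
      }
      poses$n_contacts[i] <- count_contacts(poses$pdb_path[i], st, cutoff)
    }
  }
  keys <- unique(poses[c("channel", "site")])
  scored <- list(); orderings <- list()
  for (k in seq_len(nrow(keys))) {
    sel <- poses$channel == keys$channel[k] & poses$site == keys$site[k]
    sc <- score_poses(poses[sel, ])
    scored[[k]] <- sc
    key <- keys$channel[k]
    orderings[[key]] <- c(orderings[[key]],
                          list(rank_and_select(sc)$ordering))
  }
  channel_ranks <- lapply(orderings, rank_channel)
  list(scored = do.call(rbind, scored),
       channel_ranks = channel_ranks,
       global = rank_global(channel_ranks))
}
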
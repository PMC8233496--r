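#' Neutral evolutionary probabilities (EP) for a focal sequence
#'
#' For every alignment position, computes the posterior probability of each
#' possible allele (4 nucleotides or 20 amino acids) in the focal taxon —
#' the first sequence of the alignment — given the other sequences and a
#' timetree, under the neutral substitution model. The focal tip is treated
#' as unobserved: its marginal posterior is obtained by Felsenstein pruning
#' plus a downward (outside) pass. Alleles with EP below `threshold`
#' (default 0.05) are flagged nonneutral.
#'
#' When the input tree is a phylogram, a relative-time tree is computed
#' internally with [reltime()]; branch durations are relative times and a
#' single global rate (expected substitutions per unit relative time) is
#' fitted by maximizing the likelihood of the non-focal sequences. An
#' already-ultrametric tree is used as the timetree directly (heights
#' normalized so the root is 1). With `branch_unit = "substitutions"` the
#' branch lengths are used as-is and the rate is fixed at 1.
#'
#' @param aln character matrix (taxa by sites, rows named) from
#'   [read_fasta()] or similar; first row is the focal taxon.
#' @param phy rooted `phylo`; tips must match the alignment taxa.
#' @param model a `subst_model` matching the alignment alphabet.
#' @param rate optional fixed global rate (substitutions/site per unit
#'   relative time); fitted when `NULL`.
#' @param branch_unit `"relative"` (timetree machinery, default) or
#'   `"substitutions"` (use lengths directly, rate 1).
#' @param threshold nonneutrality cutoff on the observed allele's EP.
#' @return an `ep_result`: list with `ep` (L-by-states matrix, rows sum to
#'   1), `observed` (focal allele per site, `NA` where missing),
#'   `nonneutral` (logical, `NA` where the focal state is missing),
#'   `states`, `rate`, `focal`, `t_rel` (relative node times used).
#' @export
ep_scores <- function(aln, phy, model = substitution_model("JC"),
                      rate = NULL,
                      branch_unit = c("relative", "substitutions"),
                      threshold = 0.05) {
  branch_unit <- match.arg(branch_unit)
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  if (!is.null(attr(aln, "alphabet")) &&
      attr(aln, "alphabet") != model$alphabet) {
    stop("alphabet mismatch: alignment is ", attr(aln, "alphabet"),
      " but model is ", model$alphabet)
  }
  focal <- rownames(aln)[1]
  if (!(focal %in% phy$tip.label)) {
    stop("focal taxon '", focal, "' (first alignment sequence) ",
      "is absent from the tree")
  }
  extra <- setdiff(phy$tip.label, rownames(aln))
  if (length(extra)) {
    stop("tree tip(s) absent from alignment: ", paste(extra, collapse = ", "))
  }
  phy <- .binarize(phy)
  ix0 <- .tree_index(phy)
  # branch durations on the (relative) time axis
  if (branch_unit == "substitutions") {
    dur <- ix0$blen
    if (is.null(rate)) rate <- 1
    t_rel <- NULL
  } else {
    if (length(phy$tip.label) >= 3 && !ape::is.ultrametric(phy)) {
      rt <- reltime(phy)
      t_rel <- rt$t_rel
    } else {
      depth <- .node_depths(ix0, ix0$blen)
      root_age <- max(depth)
      if (root_age <= 0) stop("tree has zero total depth")
      t_rel <- (root_age - depth) / root_age
    }
    dur <- numeric(ix0$n_all)
    nonroot <- setdiff(seq_len(ix0$n_all), ix0$root)
    dur[nonroot] <- pmax(t_rel[ix0$parent[nonroot]] - t_rel[nonroot], 0)
  }
  time_tree <- phy
  time_tree$edge.length <- dur[phy$edge[, 2]]
  # focal tip treated as missing data throughout
  aln_f <- aln
  aln_f[1, ] <- "?"
  pa <- compress_patterns(aln_f, alphabet = model$alphabet)
  if (is.null(rate)) {
    nf_tree <- ape::drop.tip(time_tree, focal)
    nf_aln <- aln[setdiff(rownames(aln), focal), , drop = FALSE]
    if (is.null(nf_tree) || length(nf_tree$tip.label) < 2) {
      stop("cannot fit a global rate with fewer than 2 non-focal taxa; ",
        "supply 'rate'")
    }
    pa_nf <- compress_patterns(nf_aln, alphabet = pa$alphabet)
    scale_ll <- function(lr) {
      tt <- nf_tree
      tt$edge.length <- nf_tree$edge.length * exp(lr)
      log_likelihood(tt, pa_nf, model)
    }
    opt <- stats::optimize(scale_ll, c(log(1e-8), log(1e3)), maximum = TRUE,
      tol = 1e-8)
    rate <- exp(opt$maximum)
  }
  sub_tree <- time_tree
  sub_tree$edge.length <- time_tree$edge.length * rate
  post <- .focal_posterior(sub_tree, pa, model, focal)
  # expand patterns back to sites
  key <- apply(aln_f, 2, paste, collapse = "\1")
  first <- !duplicated(key)
  site_of_pattern <- match(key, key[first])
  ep <- post[site_of_pattern, , drop = FALSE]
  colnames(ep) <- model$states
  obs <- toupper(aln[1, ])
  obs[!(obs %in% model$states)] <- NA
  all_missing <- apply(aln_f[-1, , drop = FALSE], 2, function(col) {
    all(is.na(match(toupper(col), model$states)))
  })
  if (any(all_missing)) {
    warning(sum(all_missing), " site(s) have no observed non-focal state; ",
      "their EP equals the stationary frequencies")
  }
  ep_obs <- rep(NA_real_, length(obs))
  hit <- !is.na(obs)
  ep_obs[hit] <- ep[cbind(which(hit), match(obs[hit], model$states))]
  structure(
    list(
      ep = ep, observed = obs, ep_observed = ep_obs,
      nonneutral = ep_obs < threshold, threshold = threshold,
      states = model$states, rate = rate, focal = focal, t_rel = t_rel
    ),
    class = "ep_result"
  )
}

# Marginal posterior of the focal tip's state for every pattern:
# inside (pruning) pass with the focal tip as missing data, then an outside
# pass down to the focal tip; per-category log constants are combined in
# log space for discrete-gamma models.
.focal_posterior <- function(phy, pa, model, focal) {
  info <- .pruning_setup(phy, pa, model)
  ix <- info$ix
  s <- info$s
  m <- info$m
  focal_id <- match(focal, ix$tip_label)
  ncat <- length(model$rates)
  logj <- array(NA_real_, c(ncat, s, m))
  for (k in seq_len(ncat)) {
    r <- model$rates[k]
    P <- lapply(seq_len(ix$n_all), function(v) {
      if (v == ix$root) NULL else transition_matrix(model, ix$blen[v] * r)
    })
    partial <- vector("list", ix$n_all)
    partial[seq_len(ix$n_tip)] <- info$tip_partial
    ls_in <- matrix(0, ix$n_all, m) # cumulative inside log constants
    for (v in ix$node_po) {
      acc <- 1
      cum <- 0
      for (ch in ix$children[[v]]) {
        acc <- acc * (P[[ch]] %*% partial[[ch]])
        cum <- cum + ls_in[ch, ]
      }
      mx <- apply(acc, 2, max)
      mx[mx == 0] <- 1
      partial[[v]] <- acc / rep(mx, each = s)
      ls_in[v, ] <- cum + log(mx)
    }
    outside <- vector("list", ix$n_all)
    ls_out <- matrix(0, ix$n_all, m)
    outside[[ix$root]] <- matrix(model$freqs, s, m)
    for (v in ix$node_pre) {
      ch <- ix$children[[v]]
      msg <- lapply(ch, function(b) P[[b]] %*% partial[[b]])
      for (i in seq_along(ch)) {
        above <- outside[[v]]
        cum <- ls_out[v, ]
        for (j in seq_along(ch)) {
          if (j == i) next
          above <- above * msg[[j]]
          cum <- cum + ls_in[ch[j], ]
        }
        raw <- crossprod(P[[ch[i]]], above)
        mx <- apply(raw, 2, max)
        mx[mx == 0] <- 1
        outside[[ch[i]]] <- raw / rep(mx, each = s)
        ls_out[ch[i], ] <- cum + log(mx)
      }
    }
    logj[k, , ] <- log(outside[[focal_id]]) +
      rep(ls_out[focal_id, ], each = s)
  }
  # mix categories and normalize over states, per pattern
  post <- matrix(0, m, s)
  for (p in seq_len(m)) {
    lj <- logj[, , p, drop = FALSE]
    dim(lj) <- c(ncat, s)
    top <- max(lj)
    w <- colSums(exp(lj - top)) # sum over categories (equal weights cancel)
    post[p, ] <- w / sum(w)
  }
  post
}

#' Tabular EP report
#'
#' TSV with one row per site: site index, observed focal allele, EP of every
#' state (fixed column order of the model alphabet), EP of the observed
#' allele, and a 0/1 nonneutral flag (`EP(observed) < threshold`).
#'
#' @param result an `ep_result`.
#' @param file optional output path.
#' @return the data frame, invisibly when `file` is given.
#' @export
ep_report <- function(result, file = NULL) {
  stopifnot(inherits(result, "ep_result"))
  epcols <- as.data.frame(result$ep)
  names(epcols) <- paste0("EP_", result$states)
  df <- cbind(
    data.frame(
      site = seq_len(nrow(result$ep)),
      observed = ifelse(is.na(result$observed), "-", result$observed),
      stringsAsFactors = FALSE
    ),
    round(epcols, 6),
    data.frame(
      EP_observed = round(result$ep_observed, 6),
      nonneutral = ifelse(is.na(result$nonneutral), NA_integer_,
        as.integer(result$nonneutral))
    )
  )
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' @export
print.ep_result <- function(x, ...) {
  nn <- sum(x$nonneutral, na.rm = TRUE)
  cat(sprintf(
    "ep_result: focal '%s', %d sites, %d states; rate %.6g; %d nonneutral site(s) (EP < %.2f)\n",
    x$focal, nrow(x$ep), length(x$states), x$rate, nn, x$threshold
  ))
  invisible(x)
}
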
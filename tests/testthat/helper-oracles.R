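# Independent oracles used across the suite. They deliberately avoid the
# package's own LP path: the system is assembled reaction-by-reaction from
# the model's raw fields and solved with pracma's simplex after shifting to
# nonnegative variables.

# maximal objective flux by an independently assembled LP (pracma::linprog)
oracle_fba <- function(model) {
  rxns <- model$rxns
  n <- nrow(rxns)
  mets <- model$mets$id
  S <- matrix(0, length(mets), n, dimnames = list(mets, rxns$id))
  for (j in seq_len(n)) {
    for (m in names(model$stoich[[rxns$id[j]]]))
      S[m, j] <- model$stoich[[rxns$id[j]]][[m]]
  }
  cc <- as.numeric(rxns$id == model$objective)
  lb <- rxns$lb; ub <- rxns$ub
  # shift x = v - lb >= 0, x <= ub - lb;  S v = 0  =>  S x = -S lb
  res <- pracma::linprog(cc = cc, A = diag(n), b = ub - lb,
                         Aeq = S, beq = -as.vector(S %*% lb),
                         maximize = TRUE, maxiter = 2000, bigM = 1e6)
  if (res$errno != 1) return(NA_real_)
  res$fval + sum(cc * lb)
}

# feasibility of {A x = 0, lb <= x <= ub} via artificial-variable mass:
# min sum(s+ + s-) s.t. A x + s+ - s- = 0; feasible iff the minimum is ~0
oracle_feasible_system <- function(A, lb, ub) {
  m <- nrow(A); n <- ncol(A)
  Aeq <- cbind(A, diag(m), -diag(m))
  cc <- c(rep(0, n), rep(1, 2 * m))
  lo <- c(lb, rep(0, 2 * m))
  hi <- c(ub, rep(1e5, 2 * m))
  res <- pracma::linprog(cc = cc, A = diag(length(cc)), b = hi - lo,
                         Aeq = Aeq, beq = -as.vector(Aeq %*% lo),
                         maximize = FALSE, maxiter = 4000, bigM = 1e6)
  if (res$errno != 1) stop("feasibility oracle did not converge")
  abs(res$fval + sum(cc * lo)) < 1e-6
}

# independent task-feasibility oracle: close every single-metabolite
# boundary reaction, open task inputs, force task outputs, test feasibility
oracle_task_feasible <- function(model, task) {
  rxns <- model$rxns
  mets <- model$mets$id
  S <- matrix(0, length(mets), nrow(rxns), dimnames = list(mets, rxns$id))
  for (j in seq_len(nrow(rxns)))
    for (m in names(model$stoich[[rxns$id[j]]]))
      S[m, j] <- model$stoich[[rxns$id[j]]][[m]]
  lb <- rxns$lb; ub <- rxns$ub
  is_exchange <- vapply(model$stoich, length, integer(1)) == 1L
  lb[is_exchange] <- 0; ub[is_exchange] <- 0
  obj <- rxns$id == model$objective
  lb[obj] <- pmin(lb[obj], 0)
  ins <- task[task$direction == "in", , drop = FALSE]
  outs <- task[task$direction == "out", , drop = FALSE]
  extra <- matrix(0, length(mets), nrow(ins) + nrow(outs))
  rownames(extra) <- mets
  for (i in seq_len(nrow(ins))) extra[ins$metabolite[i], i] <- 1
  for (i in seq_len(nrow(outs))) extra[outs$metabolite[i], nrow(ins) + i] <- -1
  oracle_feasible_system(cbind(S, extra),
                         c(lb, ins$lower, outs$lower),
                         c(ub, ins$upper, outs$upper))
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
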
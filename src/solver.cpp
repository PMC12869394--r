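// Sparse direct solver for the reduced monolithic system: Eigen SparseLU
// with AMD ordering, kept in a registry so a factorization can be reused
// across corrector passes (the backsolve is much cheaper than the factor).

// [[Rcpp::depends(RcppEigen)]]
#include <RcppEigen.h>
#include <vector>
using namespace Rcpp;

typedef Eigen::SparseLU<Eigen::SparseMatrix<double>,
                        Eigen::AMDOrdering<int>> SpLU;

static std::vector<SpLU*> g_factors;

// [[Rcpp::export]]
int cpp_splu_factor(const Eigen::MappedSparseMatrix<double>& A, int handle) {
  // release the previous factorization before computing the new one so only
  // one factor is ever resident
  if (handle >= 0 && handle < (int)g_factors.size()) {
    delete g_factors[handle];
    g_factors[handle] = nullptr;
  }
  Eigen::SparseMatrix<double> Ac = A;
  Ac.makeCompressed();
  SpLU* lu = new SpLU();
  lu->compute(Ac);
  if (lu->info() != Eigen::Success) {
    delete lu;
    stop("linear solver breakdown: sparse LU factorization failed");
  }
  if (handle >= 0 && handle < (int)g_factors.size()) {
    g_factors[handle] = lu;
    return handle;
  }
  g_factors.push_back(lu);
  return (int)g_factors.size() - 1;
}

// assemble COO triplets into a compressed sparse matrix without leaving the
// intermediate vectors to the R heap
// [[Rcpp::export]]
Eigen::SparseMatrix<double> cpp_coo_to_csc(const IntegerVector& i,
                                           const IntegerVector& j,
                                           const NumericVector& x, int n) {
  std::vector<Eigen::Triplet<double>> trip;
  trip.reserve(i.size());
  for (R_xlen_t k = 0; k < i.size(); ++k)
    trip.emplace_back(i[k], j[k], x[k]);
  Eigen::SparseMatrix<double> A(n, n);
  A.setFromTriplets(trip.begin(), trip.end());
  A.makeCompressed();
  return A;
}

// [[Rcpp::export]]
Eigen::VectorXd cpp_splu_solve(int handle, const Eigen::VectorXd& b) {
  if (handle < 0 || handle >= (int)g_factors.size() || !g_factors[handle])
    stop("invalid factorization handle");
  return g_factors[handle]->solve(b);
}
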
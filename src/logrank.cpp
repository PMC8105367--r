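#include <Rcpp.h>
using namespace Rcpp;

// Log-rank score and variance for many group assignments at once.
//
// Samples are pre-sorted by time; `grp` holds the 0-based index of each
// sample's tied-time group (ascending). For every column g the score is
// U = sum over death times of (observed - expected deaths in the high
// group) and V the hypergeometric variance, accumulated in one backward
// pass over the tied-time groups (O(n) per column, no allocations).
//
// [[Rcpp::export(name = ".logrankSweep")]]
List logrankSweep(IntegerVector grp, int nGroups, IntegerVector event,
                  LogicalMatrix incl, LogicalMatrix high) {
    const int n = incl.nrow(), G = incl.ncol();
    NumericVector U(G), V(G);
    std::vector<double> dAll(nGroups), dHigh(nGroups),
        nEnt(nGroups), hEnt(nGroups);
    for (int g = 0; g < G; ++g) {
        std::fill(dAll.begin(), dAll.end(), 0.0);
        std::fill(dHigh.begin(), dHigh.end(), 0.0);
        std::fill(nEnt.begin(), nEnt.end(), 0.0);
        std::fill(hEnt.begin(), hEnt.end(), 0.0);
        for (int i = 0; i < n; ++i) {
            if (!incl(i, g)) continue;
            const int t = grp[i];
            nEnt[t] += 1.0;
            const bool h = high(i, g);
            if (h) hEnt[t] += 1.0;
            if (event[i]) {
                dAll[t] += 1.0;
                if (h) dHigh[t] += 1.0;
            }
        }
        double nRisk = 0.0, hRisk = 0.0, u = 0.0, v = 0.0;
        for (int t = nGroups - 1; t >= 0; --t) {
            nRisk += nEnt[t];
            hRisk += hEnt[t];
            const double d = dAll[t];
            if (d > 0.0 && nRisk > 0.0) {
                const double frac = hRisk / nRisk;
                u += dHigh[t] - d * frac;
                if (nRisk > 1.0)
                    v += d * frac * (1.0 - frac) * (nRisk - d) /
                         (nRisk - 1.0);
            }
        }
        U[g] = u;
        V[g] = v;
    }
    return List::create(_["U"] = U, _["V"] = V);
}
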
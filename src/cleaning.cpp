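#include <Rcpp.h>
#include <string>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Cohesion cleaning of biclique sides against H, batched over the whole
// enumeration output.  A side is cleaned by repeatedly removing the member
// with the lowest summed signed H-weight to the rest of its side while
// that sum is non-positive (ties keep the earliest member, matching the
// R-level rule); the removed residue is re-cleaned so that a mixed side
// yields every cohesive component of size >= minSize.  Cleaned component
// pairs are deduplicated by canonical form.

namespace {

// signed weight convention: unweighted 0/1 entries map to +1/-1
double signedW(const NumericMatrix &adj, bool uw, int i, int j) {
    double w = adj(i, j);
    if (!uw) return w;
    return w > 0 ? 1.0 : -1.0;
}

// one cleaning pass to a fixpoint; input indices are 0-based and sorted
std::vector<int> cleanCore(const NumericMatrix &adj, bool uw,
                           std::vector<int> idx) {
    while (idx.size() > 1) {
        int k = (int)idx.size();
        double worst = R_PosInf;
        int worstAt = -1;
        for (int a = 0; a < k; ++a) {
            double s = 0;
            for (int b = 0; b < k; ++b)
                if (b != a) s += signedW(adj, uw, idx[a], idx[b]);
            if (s < worst) {
                worst = s;
                worstAt = a;
            }
        }
        if (worst > 0) break;
        idx.erase(idx.begin() + worstAt);
    }
    return idx;
}

std::vector<std::vector<int> > cleanComponents(const NumericMatrix &adj,
                                               bool uw,
                                               std::vector<int> idx,
                                               int minSize) {
    std::vector<std::vector<int> > out;
    while ((int)idx.size() >= minSize) {
        std::vector<int> core = cleanCore(adj, uw, idx);
        if ((int)core.size() < minSize) break;
        out.push_back(core);
        std::vector<int> rest;
        size_t ci = 0;
        for (size_t i = 0; i < idx.size(); ++i) {
            if (ci < core.size() && idx[i] == core[ci]) {
                ++ci;
            } else {
                rest.push_back(idx[i]);
            }
        }
        idx.swap(rest);
    }
    return out;
}

std::string keyOf(const std::vector<int> &a, const std::vector<int> &b) {
    std::string k;
    k.reserve(8 * (a.size() + b.size()));
    for (int v : a) {
        k += std::to_string(v);
        k += ',';
    }
    k += '|';
    for (int v : b) {
        k += std::to_string(v);
        k += ',';
    }
    return k;
}

}  // namespace

// [[Rcpp::export(name = ".clean_biclique_pairs_cpp")]]
List clean_biclique_pairs_cpp(NumericMatrix adjH, bool unweighted,
                              List sideA, List sideB, int minSize) {
    std::unordered_set<std::string> seen;
    std::vector<std::vector<int> > outA, outB;
    R_xlen_t n = sideA.size();
    for (R_xlen_t i = 0; i < n; ++i) {
        IntegerVector ra = sideA[i];
        std::vector<int> ia(ra.begin(), ra.end());
        for (int &v : ia) --v;
        std::sort(ia.begin(), ia.end());
        std::vector<std::vector<int> > compA =
            cleanComponents(adjH, unweighted, ia, minSize);
        if (compA.empty()) continue;
        IntegerVector rb = sideB[i];
        std::vector<int> ib(rb.begin(), rb.end());
        for (int &v : ib) --v;
        std::sort(ib.begin(), ib.end());
        std::vector<std::vector<int> > compB =
            cleanComponents(adjH, unweighted, ib, minSize);
        for (const std::vector<int> &ca : compA) {
            for (const std::vector<int> &cb : compB) {
                const std::vector<int> *pa = &ca, *pb = &cb;
                if (cb[0] < ca[0]) std::swap(pa, pb);
                std::string k = keyOf(*pa, *pb);
                if (!seen.insert(k).second) continue;
                outA.push_back(*pa);
                outB.push_back(*pb);
            }
        }
    }
    R_xlen_t m = (R_xlen_t)outA.size();
    List resA(m), resB(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        IntegerVector a(outA[i].size()), b(outB[i].size());
        for (size_t k = 0; k < outA[i].size(); ++k) a[k] = outA[i][k] + 1;
        for (size_t k = 0; k < outB[i].size(); ++k) b[k] = outB[i][k] + 1;
        resA[i] = a;
        resB[i] = b;
    }
    return List::create(_["sideA"] = resA, _["sideB"] = resB);
}
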
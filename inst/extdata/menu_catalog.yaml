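# m4RH Tanzania menu catalog.
# Code 66 (family planning / pregnancy prevention methods) is the documented
# production code; other numeric codes are plausible synthetic stand-ins.
# "About family planning" and "Youth" menus were added to the service in 2015.
keyword: m4rh
misspellings: [mr4h, m4hr, mrh4, mfrh]
nodes:
  - {code: "00", label: Main menu, level: main, parent: m4rh}
  - {code: "11", label: About family planning, level: submenu, parent: "00", active_from: 2015-01-01}
  - {code: "66", label: Family planning methods, level: submenu, parent: "00"}
  - {code: "77", label: Youth, level: submenu, parent: "00", active_from: 2015-01-01}
  - {code: "88", label: Role model stories, level: submenu, parent: "00"}
  - {code: "99", label: Clinic locations, level: submenu, parent: "00"}
  - {code: "12", label: Family planning basics, level: content, parent: "11", active_from: 2015-01-01}
  - {code: "13", label: Family planning myths, level: content, parent: "11", active_from: 2015-01-01}
  - {code: "61", label: Natural family planning, level: content, parent: "66"}
  - {code: "62", label: Condom, level: content, parent: "66"}
  - {code: "63", label: Lactational amenorrhea method, level: content, parent: "66"}
  - {code: "64", label: Emergency contraception, level: content, parent: "66"}
  - {code: "65", label: Permanent, level: content, parent: "66"}
  - {code: "67", label: Implant, level: content, parent: "66"}
  - {code: "68", label: Injectable, level: content, parent: "66"}
  - {code: "69", label: Pills, level: content, parent: "66"}
  - {code: "70", label: Intrauterine contraceptive device, level: content, parent: "66"}
  - {code: "71", label: Puberty, level: content, parent: "77", active_from: 2015-01-01}
  - {code: "72", label: About sex, level: content, parent: "77", active_from: 2015-01-01}
  - {code: "73", label: Choices, level: content, parent: "77", active_from: 2015-01-01}
  - {code: "81", label: Role model story 1, level: content, parent: "88"}
  - {code: "82", label: Role model story 2, level: content, parent: "88"}
  - {code: ward, label: Ward lookup, level: ward_lookup, parent: "99"}
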